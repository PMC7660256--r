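---
title: "Methods: regulon expansion from genome-wide binding screens"
author: "regulonscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon expansion from genome-wide binding screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscan)
```

## The problem

A bacterial transcription factor (TF) typically controls a set of
transcription units — its regulon — far larger than the handful of targets
catalogued from promoter-by-promoter genetics. Genomic SELEX (gSELEX)
screens close that gap *in vitro*: genome fragments bound by the purified TF
are affinity-enriched and mapped back to the genome, here via a tiling-array
readout that turns the enriched pool into a per-position binding-intensity
profile. `regulonscan` implements the dry-lab arm of such a screen for the
pyruvate-sensing repressor PdhR of *Escherichia coli* K-12, generalised so
that any TF with a gapped palindromic recognition element can be analysed:
peak selection, genomic-context typing, regulon-size bounds, and
recognition-element characterisation, plus a synthetic-data generator that
stands in for the wet experiment.

## Peak selection

A `binding_track` is an evenly spaced non-negative intensity vector
(arbitrary, upstream-normalised fluorescence-ratio units). `call_peaks()`
reports every local maximum at or above a hard intensity `cutoff`
(default 500, the screen's published operating point, applied inclusively —
every catalogued site reaches it), merging maxima closer than
`min_separation` (default 500 bp, the fragment/probe scale) by keeping the
higher, ties to the leftmost. Plateaus report their leftmost probe. There is
no FDR machinery by design: the screen's decision rule is a single hard
cutoff, and the caller reproduces exactly that. How the original array
ratios were smoothed into the published profile is not recorded anywhere we
can reach; the caller is therefore a documented reconstruction, validated
against an exhaustive brute-force local-maximum oracle on short tracks and
against planted peaks on synthetic data, not against the original array
files.

Paired screens (with and without the effector ligand) are compared per site
by `effector_response()`: the retained fraction
$(I_{\mathrm{eff}}+c)/(I_{\mathrm{no\,eff}}+c)$ with shared pseudocount $c$
(default 0), and a `sensitive` call when the fraction drops below a
threshold (default 0.5). The published table's first intensity column is
treated as the no-effector screen and the second as + effector; the printed
column headers say otherwise, but the text and profile figure are
unambiguous that intensities *fall* with the effector, and the first column
is consistently the larger.

## Genomic-context typing and regulon bounds

Gene bodies are CDS extents; "upstream" means the 5′ intergenic side —
promoters, UTRs and transcription starts are not modelled, and no maximum
upstream distance is imposed (a configurable limit would only matter on
gene-dense genomes; the published typing applies none). A peak is typed:

* **A** — intergenic, upstream of both flanks (divergent spacer): up to two
  targets;
* **B** — intergenic, upstream of exactly one flank (tandem spacer): one
  target;
* **C** — intergenic, upstream of neither (convergent spacer): none;
* **D** — inside an ORF: the host gene is recorded for reporting but
  contributes no target.

With $n_A$ and $n_B$ sites of types A and B, the regulon size lies between
$n_A + n_B$ (each upstream site regulates at least one unit) and
$2 n_A + n_B$ (every divergent site regulates both flanks). No attempt is
made to decide which of a divergent pair is the real target — that requires
in-vivo expression data, which is out of scope here and carried only as
optional annotation. When genes overlap, the host is the overlapping gene
with the smallest start (a deterministic, documented tie-break). The genome
is linear by default; `circular = TRUE` wraps the flanking-gene search, and
on a linear genome a missing flank is classified from the existing side
with a warning.

## The recognition box and conservation scoring

The recognition element is a degenerate palindrome: `palindrome_box(arm,
spacer_length)` builds `arm + spacer + reverse-complement(arm)`, which is
self-reverse-complementary by construction. The default is the 17-bp PdhR
box `AATTGGTnnnACCAATT` with 14 informative (non-spacer) positions; the
literature's 15-bp variant is one configuration away
(`palindrome_box("ATTGGT", 3)`). The 17-bp form is the default because
every catalogued site sequence is 17 nt and every printed denominator is 14.

`score_against_box()` counts case-insensitive matches at informative
positions only; any non-ACGT letter (including `n`) is a mismatch.
`render_match()` reproduces the catalogue's casing convention — uppercase
where an informative position matches, lowercase elsewhere.
`scan_window()` evaluates every offset on both strands and keeps the best
match (ties: smaller offset, then plus strand); since the box is
self-reverse-complementary the two strands always tie on score, so reported
matches default to the plus strand, with positions given as the plus-strand
coordinate of the leftmost base. Sites scoring below a reporting floor
(default 7/14, the weakest catalogued score) print as `-` in report tables.

`build_matrix()` tallies per-position base counts (plus a pseudocount) and
information content $2 + \sum_b p_b \log_2 p_b$ bits against a uniform
background. `derive_consensus()` is a majority-rule reduction: the modal
base where its frequency reaches the threshold (default 0.75), else `n`.
This is an in-house stand-in for the external motif-discovery program used
in the original analysis, validated on the catalogue itself: the 28 printed
site sequences yield a consensus whose positions 5–7 and 11–13 read
`GGT…ACC`, the fully conserved 9-bp core.

## The packaged catalogue and its one anomaly

`pdhr_table1()` ships the 35 published PdhR sites (7 A, 9 B, 19 D; type C
was not observed). `fixture_annotation()` synthesises gene coordinates from
the printed flanking-gene arrows — only order and orientation relative to
each peak are real, which is all the typing uses; the file and loader say
so. `validate_fixture()` re-scores and re-renders every printed sequence:
27 of 28 reproduce byte-for-byte. The acpP row (`AcaTGGTctgACCgctt 8/14`)
is internally inconsistent as published — its printed count equals its
uppercase-letter count (8), yet its trailing lowercase `tt` coincides with
the consensus base `T`, so rescoring the letters gives 10/14. We transcribe
the row verbatim and flag it as the single expected discrepancy rather than
"correcting" data we cannot verify.

## The synthetic-data generator

`simulate_genome()` and `simulate_tracks()` emulate the screen's
statistical structure, not its biochemistry:

* genes are laid out as couples whose internal orientation
  (divergent/tandem/convergent) is drawn from `orientation_mix`
  (default 0.25/0.5/0.25), with couples hosting planted intergenic sites
  forced to the required orientation — so the realised mix is exact for
  unconstrained couples and the guarantee is exact for planted contexts;
* gene lengths are uniform in 600–1200 bp and spacers in 250–450 bp
  (typical enterobacterial scales, and wide enough for a box plus margins);
* each planted site is a box instance with exactly the requested number of
  informative-position mutations (drawn without replacement, mutated to a
  different base) and a uniformly random spacer;
* tracks are independent per-probe Gaussian noise (mean 50, sd 20, clipped
  at 0 — the simplest model that exercises the cutoff logic; the source
  experiment documents no noise model) plus one Gaussian bump per site
  (sigma 150 bp, the 200–300-bp fragment scale) of its amplitude, scaled by
  `effector_retention` (default 0.2) in the + effector track;
* probes are spaced 100 bp apart, the published array's genome-wide density.

The default layout plants 20 sites (4 A, 5 B, 11 D — the catalogue's
proportions), 0–3 mismatches, amplitudes 550–9000 units spanning the
published intensity range, i.e. apex signal-to-noise well above 5.
Everything is reproducible: the genome draws from `seed`, the tracks from
`seed + 1`, and identical configurations give byte-identical FASTA, GFF3,
bedGraph and TSV outputs.

What passing the end-to-end recovery test (≥ 95 % of planted sites
recovered with correct type and exact conservation score) shows is that the
pipeline's logic is sound under the generator's assumptions — independent
Gaussian noise, isolated Gaussian peaks, exact motif planting. Real
tiling-array data add probe-sequence effects, correlated noise, copy-number
bias and overlapping binding events, none of which the generator models, so
recovery rates on real data are expected to be lower.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout; BED input is converted on
  read, bedGraph written 0-based half-open as its format requires.
* The cutoff is inclusive (≥); the published phrasing is ambiguous and the
  weakest catalogued intensity (509) makes inclusivity unobservable there.
* Peak merging is greedy by intensity (ties to the leftmost), which makes
  peak count provably non-increasing in the cutoff.
* Scan ties resolve to the smaller offset, then the plus strand. For a
  self-reverse-complementary box a window and its reverse complement always
  tie, so strand labels on reported matches are a convention, not a claim.
* The consensus threshold default (0.75) is the smallest round majority at
  which the catalogue's core `GGT…ACC` is called while genuinely degenerate
  positions fall to `n`.
* Problem sizes in the tests (20-site simulations on 200-kb genomes,
  10 000 random 17-mers, 200 scanned windows, tracks up to 10 kb against
  brute-force oracles) were chosen as the smallest scales at which the
  properties are meaningfully exercised.

## Known limitations

* The peak caller reconstructs an undocumented smoothing step; agreement
  with the published catalogue is at the peak-table level, not the raw-array
  level.
* Typing anchors on CDS boundaries; screens on organisms with long 5′ UTRs
  or extensive operon leaders may need the configurable upstream limit.
* `derive_consensus()` is majority-rule, not an information-theoretic or
  enrichment-based motif finder; it assumes the input sites are already
  aligned (all exactly one box length).
* The effector comparison is a per-site intensity ratio; it does not model
  binding thermodynamics or effector dose response.
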