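Package: regulonscan
Title: Transcription-Factor Regulon Expansion from Genome-Wide Binding Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expanding a bacterial transcription-factor regulon from
    genome-wide binding-intensity data, modelled on genomic SELEX (gSELEX)
    tiling-array screens. Calls binding peaks from intensity tracks with a hard
    cutoff, classifies each binding site by genomic context (upstream of a
    divergent gene pair, upstream of a single gene, downstream of a convergent
    pair, or inside an open reading frame), bounds the regulon size from the
    context counts, scores 17-bp sites against a degenerate palindromic
    recognition box (default the PdhR box AATTGGTnnnACCAATT, 14 informative
    positions), scans sequence windows on both strands, builds count and
    information matrices and derives majority-rule consensus strings, and
    compares paired screens with and without an effector ligand. Ships the
    published PdhR binding-site table as a validated fixture and a
    synthetic-data generator (annotated genome, planted motif instances,
    Gaussian intensity peaks over noise) so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
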