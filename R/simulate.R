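#' Configuration for the synthetic gSELEX-style dataset
#'
#' Bundles every knob of the generator. Defaults emulate the screened system
#' at desk scale: a gene-dense bacterial genome segment, 17-bp box instances
#' planted with controlled mismatch counts, and tiling-array-like intensity
#' profiles — Gaussian peaks of a few hundred to a few thousand units over a
#' low noise floor, shrinking under the effector condition.
#'
#' @param seed integer seed; the generator is fully reproducible.
#' @param genome_length genome size in bp.
#' @param n_genes number of genes to place (rounded up to even; genes are laid
#'   out as consecutive couples whose internal orientation follows
#'   `orientation_mix`).
#' @param orientation_mix named fractions (`divergent`, `tandem`,
#'   `convergent`) for unconstrained gene couples; must sum to 1.
#' @param gc_content background GC fraction.
#' @param planted_sites data.frame with columns `type` (`"A"/"B"/"C"/"D"`),
#'   `mismatches` (0-14 informative-position mutations) and `amplitude`
#'   (apex intensity units above background).
#' @param peak_width Gaussian sigma of each intensity bump, in bp (fragment
#'   scale of a 200-300 bp library).
#' @param background_mean,background_sd per-probe background noise (normal,
#'   clipped at 0).
#' @param effector_retention multiplicative factor on planted amplitudes in
#'   the + effector track (the effector weakens binding).
#' @param probe_step probe spacing in bp (tiling-array resolution).
#' @param gene_length_range,spacer_range uniform ranges for gene body and
#'   intergenic spacer lengths, in bp.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 200000L,
                              n_genes = 80L,
                              orientation_mix = c(divergent = 0.25,
                                                  tandem = 0.5,
                                                  convergent = 0.25),
                              gc_content = 0.5,
                              planted_sites = default_planted_sites(),
                              peak_width = 150,
                              background_mean = 50,
                              background_sd = 20,
                              effector_retention = 0.2,
                              probe_step = 100L,
                              gene_length_range = c(600L, 1200L),
                              spacer_range = c(250L, 450L)) {
  stopifnot(all(c("divergent", "tandem", "convergent") %in%
                  names(orientation_mix)),
            abs(sum(orientation_mix) - 1) < 1e-8,
            all(orientation_mix >= 0), all(orientation_mix <= 1),
            gc_content >= 0, gc_content <= 1,
            peak_width > 0, background_sd >= 0,
            effector_retention >= 0, probe_step >= 1)
  if (nrow(planted_sites)) {
    stopifnot(all(planted_sites$type %in% c("A", "B", "C", "D")),
              all(planted_sites$mismatches >= 0),
              all(planted_sites$mismatches <= 14),
              all(planted_sites$amplitude > 0))
  }
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes), orientation_mix = orientation_mix,
                 gc_content = gc_content, planted_sites = planted_sites,
                 peak_width = peak_width, background_mean = background_mean,
                 background_sd = background_sd,
                 effector_retention = effector_retention,
                 probe_step = as.integer(probe_step),
                 gene_length_range = as.integer(gene_length_range),
                 spacer_range = as.integer(spacer_range)),
            class = "simulation_config")
}

#' Default planted-site layout
#'
#' Twenty sites echoing the published type proportions (4 type-A, 5 type-B,
#' 11 type-D), with 0-3 informative-position mismatches and amplitudes
#' spanning the published intensity range (roughly 500-10000 units, i.e.
#' apex signal-to-noise well above 5 over the default noise floor).
#'
#' @return data.frame with columns `type`, `mismatches`, `amplitude`.
#' @export
default_planted_sites <- function() {
  data.frame(
    type = c(rep("A", 4), rep("B", 5), rep("D", 11)),
    mismatches = c(0, 2, 3, 1, 0, 1, 2, 3, 1, 2, 3, 0, 1, 2, 3, 1, 2, 0, 3, 2),
    amplitude = c(9000, 700, 600, 1500, 3000, 900, 650, 1200, 800,
                  1100, 550, 2000, 750, 950, 600, 1300, 850, 4000, 700, 1600))
}

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# A box instance with exactly `mismatches` informative-position mutations and
# a uniformly random spacer.
planted_motif <- function(box, mismatches) {
  chars <- box_chars(box)
  spacer <- setdiff(seq_len(box$length), box$informative)
  chars[spacer] <- sample(c("A", "C", "G", "T"), length(spacer), replace = TRUE)
  if (mismatches > 0) {
    pos <- sample(box$informative, mismatches)
    chars[pos] <- vapply(chars[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  paste(toupper(chars), collapse = "")
}

#' Simulate an annotated genome with planted binding sites
#'
#' Lays out genes left to right as couples separated by spacers, assigns each
#' couple's internal orientation (divergent/tandem/convergent), and writes a
#' box instance with the requested mismatch count into a location realising
#' each planted site's context type: type-A/B/C sites go into a
#' within-couple spacer of the required orientation (divergent, tandem,
#' convergent respectively), type-D sites into a gene body. The remaining
#' couples draw their orientation from `orientation_mix`. Fully reproducible
#' under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param box the [palindrome_box()] to plant.
#' @return List with `genome` (character DNA string), `annotation`
#'   (a [genome_annotation()]) and `truth` (data.frame: `position` of each
#'   planted motif's first base, `apex` of its intensity bump, `type`,
#'   `mismatches`, `sequence`, `amplitude`).
#' @export
simulate_genome <- function(config, box = palindrome_box()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ps <- config$planted_sites
  n_genes <- config$n_genes + config$n_genes %% 2L
  n_couples <- n_genes %/% 2L
  need_spacer <- sum(ps$type %in% c("A", "B", "C"))
  need_gene <- sum(ps$type == "D")
  if (need_spacer > n_couples || need_gene > n_genes)
    stop("not enough genes (", n_genes, ") for ", nrow(ps), " planted sites")
  max_span <- n_genes * max(config$gene_length_range) +
    (2L * n_couples) * max(config$spacer_range) + 1000L
  if (config$genome_length < max_span)
    stop("genome_length ", config$genome_length, " too short for ", n_genes,
         " genes with the configured length ranges (need <= ", max_span, ")")

  # couple orientations: planted A/B/C sites claim the first couples
  orient <- character(n_couples)
  spacer_sites <- which(ps$type %in% c("A", "B", "C"))
  orient[seq_along(spacer_sites)] <-
    c(A = "divergent", B = "tandem", C = "convergent")[ps$type[spacer_sites]]
  free <- which(orient == "")
  orient[free] <- sample(names(config$orientation_mix), length(free),
                         replace = TRUE, prob = config$orientation_mix)
  strand_for <- function(o) switch(o, divergent = c("-", "+"),
                                   tandem = c("+", "+"),
                                   convergent = c("+", "-"))

  glen <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 n_genes, replace = TRUE)
  slen <- sample(seq(config$spacer_range[1], config$spacer_range[2]),
                 2L * n_couples, replace = TRUE)
  slen <- pmax(slen, 3L * box$length)

  genes <- vector("list", n_genes)
  truth <- vector("list", nrow(ps))
  motif_at <- integer(0)          # positions (first base) of planted motifs
  motif_seq <- character(0)
  cursor <- 1L
  gi <- 0L
  d_sites <- which(ps$type == "D")
  d_queue <- d_sites
  for (cp in seq_len(n_couples)) {
    cursor <- cursor + slen[2L * cp - 1L]   # leading spacer
    st <- strand_for(orient[cp])
    starts <- integer(2)
    for (k in 1:2) {
      gi <- gi + 1L
      starts[k] <- cursor
      genes[[gi]] <- data.frame(id = sprintf("gene%03d", gi),
                                start = cursor, end = cursor + glen[gi] - 1L,
                                strand = st[k], product = NA_character_,
                                operon = NA_character_)
      # plant a type-D site mid-ORF of this gene if one is queued
      if (length(d_queue) && cp > length(spacer_sites)) {
        si <- d_queue[1L]; d_queue <- d_queue[-1L]
        pos <- cursor + glen[gi] %/% 2L
        sq <- planted_motif(box, ps$mismatches[si])
        truth[[si]] <- data.frame(position = pos, type = "D",
                                  mismatches = ps$mismatches[si],
                                  sequence = sq, amplitude = ps$amplitude[si])
        motif_at <- c(motif_at, pos); motif_seq <- c(motif_seq, sq)
      }
      cursor <- cursor + glen[gi]
      if (k == 1L) {
        gap <- slen[2L * cp]
        if (cp <= length(spacer_sites)) {   # plant in the within-couple spacer
          si <- spacer_sites[cp]
          pos <- cursor + gap %/% 2L
          sq <- planted_motif(box, ps$mismatches[si])
          truth[[si]] <- data.frame(position = pos, type = ps$type[si],
                                    mismatches = ps$mismatches[si],
                                    sequence = sq, amplitude = ps$amplitude[si])
          motif_at <- c(motif_at, pos); motif_seq <- c(motif_seq, sq)
        }
        cursor <- cursor + gap
      }
    }
  }
  if (length(d_queue))
    stop("could not place ", length(d_queue), " type-D site(s): ",
         "all gene bodies are claimed by spacer-site couples; increase n_genes")

  genome <- rand_dna(config$genome_length, config$gc_content)
  for (i in seq_along(motif_at)) {
    substr(genome, motif_at[i], motif_at[i] + box$length - 1L) <- motif_seq[i]
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(position = integer(), type = character(),
                           mismatches = integer(), sequence = character(),
                           amplitude = numeric())
  truth$apex <- truth$position + box$length %/% 2L
  truth <- truth[, c("position", "apex", "type", "mismatches", "sequence",
                     "amplitude")]
  list(genome = genome,
       annotation = genome_annotation(do.call(rbind, genes),
                                      config$genome_length),
       truth = truth)
}

#' Simulate paired binding-intensity tracks from ground truth
#'
#' Each track is independent per-probe normal background noise (clipped at 0)
#' plus, for every planted site, a Gaussian bump of its amplitude centred on
#' its apex; the + effector track scales every amplitude by
#' `config$effector_retention`. Seeded from `config$seed` (offset so genome
#' and tracks draw independent streams).
#'
#' @param truth data.frame from [simulate_genome()] (`apex`, `amplitude`).
#' @param config a [simulation_config()].
#' @return List of two [binding_track()]s: `no_effector` and `effector`.
#' @export
simulate_tracks <- function(truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  n <- ceiling(config$genome_length / config$probe_step)
  pos <- (seq_len(n) - 1L) * config$probe_step + 1L
  bump <- numeric(n)
  for (i in seq_len(nrow(truth))) {
    bump <- bump + truth$amplitude[i] *
      exp(-(pos - truth$apex[i])^2 / (2 * config$peak_width^2))
  }
  noise1 <- pmax(0, rnorm(n, config$background_mean, config$background_sd))
  noise2 <- pmax(0, rnorm(n, config$background_mean, config$background_sd))
  list(no_effector = binding_track(noise1 + bump, step = config$probe_step,
                                   condition = "no_effector"),
       effector = binding_track(noise2 + config$effector_retention * bump,
                                step = config$probe_step,
                                condition = "effector"))
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa` (FASTA, via \pkg{Biostrings}), `genes.gff3`,
#' `track_no_effector.bedGraph`, `track_effector.bedGraph` and `truth.tsv`.
#' Identical config + seed give byte-identical files.
#'
#' @param sim result of [simulate_genome()].
#' @param tracks result of [simulate_tracks()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(sim$genome)
  names(dna) <- "genome"
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fa"))
  write_annotation(sim$annotation, file.path(dir, "genes.gff3"))
  write_track(tracks$no_effector, file.path(dir, "track_no_effector.bedGraph"))
  write_track(tracks$effector, file.path(dir, "track_effector.bedGraph"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
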