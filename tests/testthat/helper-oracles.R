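# Independent oracles and small fixture builders, kept deliberately separate
# from the package's implementation paths.

# Reverse complement through Biostrings (oracle route).
oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
}

# Conservation scoring recomputed from first principles: build the full
# consensus with Biostrings, compare character vectors position by position,
# skip the spacer.
oracle_score <- function(site, arm = "AATTGGT", spacer = 3L) {
  consensus <- paste0(arm, strrep("N", spacer), oracle_revcomp(arm))
  cc <- strsplit(consensus, "")[[1]]
  sc <- strsplit(toupper(site), "")[[1]]
  stopifnot(length(cc) == length(sc))
  sum(cc != "N" & sc == cc)
}

# Exhaustive best-match search over every offset and both strands.
oracle_scan <- function(sequence, arm = "AATTGGT", spacer = 3L) {
  L <- 2L * nchar(arm) + spacer
  best <- list(matches = -1L)
  for (off in seq_len(nchar(sequence) - L + 1L)) {
    win <- toupper(substr(sequence, off, off + L - 1L))
    for (strand in c("+", "-")) {
      site <- if (strand == "+") win else oracle_revcomp(win)
      m <- oracle_score(site, arm, spacer)
      if (m > best$matches) best <- list(matches = m, offset = off,
                                         strand = strand, site = site)
    }
  }
  best
}

# Exhaustive peak finding: every probe that is >= cutoff, strictly above its
# left neighbour (leftmost of a plateau) and >= its right neighbour; then
# repeatedly drop the weakest candidate lying within min_separation of a
# better one (higher intensity; ties broken to the smaller position).
oracle_peaks <- function(values, step, cutoff, min_separation) {
  n <- length(values)
  cand <- integer()
  for (i in seq_len(n)) {
    l <- if (i > 1) values[i - 1] else -Inf
    r <- if (i < n) values[i + 1] else -Inf
    if (values[i] >= cutoff && values[i] > l && values[i] >= r)
      cand <- c(cand, i)
  }
  pos <- (cand - 1L) * step + 1L
  # merge: strongest first (ties to the smaller position); a maximum survives
  # only if no already-accepted maximum lies within min_separation
  accepted_pos <- numeric(0)
  accepted_val <- numeric(0)
  for (i in order(-values[cand], pos)) {
    if (length(accepted_pos) == 0 ||
        min(abs(accepted_pos - pos[i])) >= min_separation) {
      accepted_pos <- c(accepted_pos, pos[i])
      accepted_val <- c(accepted_val, values[cand[i]])
    }
  }
  o <- order(accepted_pos)
  data.frame(position = accepted_pos[o], intensity = accepted_val[o])
}

# Two-gene toy annotation used across context tests.
toy_annotation <- function() {
  genome_annotation(
    data.frame(id = c("g1", "g2"), start = c(100L, 600L), end = c(400L, 900L),
               strand = c("+", "-")),
    genome_length = 1000)
}

# Random annotation with non-overlapping genes, for property tests.
random_annotation <- function(n_genes, genome_length) {
  pitch <- genome_length %/% (n_genes + 1L)
  starts <- pitch * seq_len(n_genes) - pitch %/% 2L
  width <- sample(seq(20L, max(21L, pitch %/% 2L)), n_genes, replace = TRUE)
  genome_annotation(
    data.frame(id = sprintf("g%d", seq_len(n_genes)),
               start = starts, end = pmin(starts + width, genome_length),
               strand = sample(c("+", "-"), n_genes, replace = TRUE)),
    genome_length)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
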