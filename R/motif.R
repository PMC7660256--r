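# Reverse complement for plain character DNA, preserving case; letters outside
# ACGTacgt (ambiguity codes) are left unchanged and score as mismatches.
revcomp_chr <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(strsplit(x, "", fixed = TRUE),
                function(ch) paste(rev(ch), collapse = ""), ""))
}

#' The degenerate palindromic recognition box
#'
#' A gapped palindrome: two arms of equal length around an unconstrained
#' spacer, where the right arm is the reverse complement of the left. The
#' default is the 17-bp PdhR box `AATTGGTnnnACCAATT` (arm `AATTGGT`, 3-nt
#' spacer), whose 14 non-spacer positions are the informative positions used
#' for conservation scoring. A 15-bp variant is available via
#' `palindrome_box("ATTGGT", 3)`.
#'
#' @param arm left-arm DNA string (A/C/G/T).
#' @param spacer_length spacer width in nt (>= 0).
#' @return An object of class `palindrome_box` with elements `arm`,
#'   `spacer_length`, `consensus` (full consensus, spacer as `n`), `length`,
#'   and `informative` (indices of the non-spacer positions).
#' @export
#' @examples
#' box <- palindrome_box()
#' box$consensus            # "AATTGGTnnnACCAATT"
#' length(box$informative)  # 14
palindrome_box <- function(arm = "AATTGGT", spacer_length = 3L) {
  arm <- toupper(arm)
  if (!grepl("^[ACGT]+$", arm)) stop("arm must be a non-empty A/C/G/T string")
  spacer_length <- as.integer(spacer_length)
  if (is.na(spacer_length) || spacer_length < 0)
    stop("spacer_length must be a non-negative integer")
  k <- nchar(arm)
  consensus <- paste0(arm, strrep("n", spacer_length), toupper(revcomp_chr(arm)))
  structure(list(arm = arm, spacer_length = spacer_length,
                 consensus = consensus, length = 2L * k + spacer_length,
                 informative = c(seq_len(k), (k + spacer_length) + seq_len(k))),
            class = "palindrome_box")
}

#' @export
print.palindrome_box <- function(x, ...) {
  cat(sprintf("palindrome_box: %s (%d bp, %d informative positions)\n",
              x$consensus, x$length, length(x$informative)))
  invisible(x)
}

box_chars <- function(box) strsplit(box$consensus, "", fixed = TRUE)[[1]]

site_chars <- function(site, box) {
  if (length(site) != 1L || !is.character(site))
    stop("site must be a single character string")
  if (nchar(site) != box$length)
    stop("site length ", nchar(site), " != box length ", box$length)
  strsplit(site, "", fixed = TRUE)[[1]]
}

#' Conservation score of a site against the box
#'
#' Counts, case-insensitively, the informative (non-spacer) positions at which
#' the site matches the box consensus. Spacer positions are never scored, and
#' any letter other than A/C/G/T (including `n`) counts as a mismatch.
#' Rendered as `"matches/informative"`, e.g. `"14/14"`.
#'
#' @param site DNA string exactly as long as the box.
#' @param box a [palindrome_box()].
#' @return Object of class `conservation_score`: list with `matches`,
#'   `informative`, `rendered`.
#' @export
#' @examples
#' score_against_box("AATTGGTAAGACCAATT")$rendered  # "14/14"
#' score_against_box("TCCTGGTCATAGCACCT")$matches   # 8
score_against_box <- function(site, box = palindrome_box()) {
  sc <- toupper(site_chars(site, box))
  bc <- box_chars(box)
  info <- box$informative
  matches <- sum(sc[info] == bc[info])
  structure(list(matches = matches, informative = length(info),
                 rendered = sprintf("%d/%d", matches, length(info))),
            class = "conservation_score")
}

#' @export
print.conservation_score <- function(x, ...) {
  cat("conservation:", x$rendered, "\n")
  invisible(x)
}

#' @export
format.conservation_score <- function(x, ...) x$rendered

#' Render a site with match-case annotation
#'
#' Uppercases the informative positions that match the box consensus and
#' lowercases everything else (mismatches and the spacer), the convention the
#' published binding-site table prints. Uppercasing the output recovers the
#' input sequence.
#'
#' @inheritParams score_against_box
#' @return Case-annotated string, e.g. `"AATTGGTaagACCAATT"`.
#' @export
render_match <- function(site, box = palindrome_box()) {
  sc <- toupper(site_chars(site, box))
  bc <- box_chars(box)
  out <- tolower(sc)
  hit <- box$informative[sc[box$informative] == bc[box$informative]]
  out[hit] <- sc[hit]
  paste(out, collapse = "")
}

#' Scan a sequence window for the best box match
#'
#' Evaluates every offset of the window on both strands and returns the
#' highest-scoring match. Ties are broken to the smaller offset, then to the
#' plus strand. Genome positions refer to the plus-strand coordinate of the
#' match's leftmost base: `origin + offset - 1` for both strands.
#'
#' @param sequence DNA string at least as long as the box.
#' @param box a [palindrome_box()].
#' @param origin 1-based genome coordinate of the window's first base, used to
#'   report `genome_position`.
#' @return Object of class `motif_match`: list with `site_sequence` (the
#'   matched site read 5'->3' on its strand), `score`
#'   ([score_against_box()] result), `genome_position`, `offset`, `strand`
#'   and `rendered_sequence`.
#' @export
scan_window <- function(sequence, box = palindrome_box(), origin = 1L) {
  if (nchar(sequence) < box$length)
    stop("window (", nchar(sequence), " nt) shorter than box (",
         box$length, " nt)")
  seq_up <- toupper(sequence)
  n_off <- nchar(sequence) - box$length + 1L
  best <- NULL
  for (off in seq_len(n_off)) {
    win <- substr(seq_up, off, off + box$length - 1L)
    for (strand in c("+", "-")) {
      site <- if (strand == "+") win else revcomp_chr(win)
      m <- score_against_box(site, box)$matches
      if (is.null(best) || m > best$matches) {
        best <- list(matches = m, offset = off, strand = strand, site = site)
      }
    }
  }
  score <- score_against_box(best$site, box)
  structure(list(site_sequence = best$site,
                 score = score,
                 genome_position = as.integer(origin) + best$offset - 1L,
                 offset = best$offset,
                 strand = best$strand,
                 rendered_sequence = render_match(best$site, box)),
            class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("motif_match: %s  %s  pos %d (%s)\n", x$rendered_sequence,
              x$score$rendered, x$genome_position, x$strand))
  invisible(x)
}

#' Build a base-count / information-content matrix from aligned sites
#'
#' Tallies A/C/G/T per position over a collection of equal-length sites (plus
#' a pseudocount per cell) and computes the per-position information content
#' against a uniform background, `IC = 2 + sum_b p_b log2 p_b`, in bits
#' within `[0, 2]`. The matrix is the input to logo rendering and to
#' [derive_consensus()].
#'
#' @param sites character vector of equal-length DNA strings (case ignored;
#'   non-ACGT letters are dropped from the column tally).
#' @param pseudocount added to every cell of the count matrix.
#' @return Object of class `motif_matrix`: list with `counts` (4 x L matrix,
#'   rows A,C,G,T), `pseudocount`, `n_sites`, and `ic` (length-L numeric).
#' @export
build_matrix <- function(sites, pseudocount = 0) {
  if (length(sites) < 1L) stop("at least one site is required")
  stopifnot(pseudocount >= 0)
  len <- unique(nchar(sites))
  if (length(len) != 1L)
    stop("sites have unequal lengths: ", paste(len, collapse = ", "))
  mat <- matrix(pseudocount, nrow = 4, ncol = len,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  chars <- do.call(rbind, strsplit(toupper(sites), "", fixed = TRUE))
  for (b in rownames(mat)) mat[b, ] <- mat[b, ] + colSums(chars == b)
  p <- sweep(mat, 2, colSums(mat), "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- pmax(0, pmin(2, 2 + colSums(plogp)))
  structure(list(counts = mat, pseudocount = pseudocount,
                 n_sites = length(sites), ic = ic),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix: %d sites x %d positions (pseudocount %g)\n",
              x$n_sites, ncol(x$counts), x$pseudocount))
  cat("IC (bits):", paste(formatC(x$ic, format = "f", digits = 2),
                          collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.motif_matrix <- function(x, ...) {
  graphics::barplot(x$ic, names.arg = seq_along(x$ic),
                    xlab = "position", ylab = "information content (bits)",
                    ylim = c(0, 2), ...)
  invisible(x)
}

#' Write a motif matrix as TSV
#'
#' One row per position with A/C/G/T counts and the information content,
#' loadable by common logo-rendering tools.
#'
#' @param matrix a [build_matrix()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motif_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "motif_matrix"))
  df <- data.frame(position = seq_len(ncol(matrix$counts)),
                   t(matrix$counts), IC = matrix$ic)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a degenerate consensus from a count matrix
#'
#' Per position, the modal base if its frequency reaches
#' `majority_threshold`, else `n`; a tie at the mode also yields `n`. This is
#' an in-house majority-rule stand-in for external motif-discovery tools,
#' validated against the published 17-bp consensus and its fully conserved
#' `GGTnnnACC` core.
#'
#' @param matrix a [build_matrix()] result.
#' @param majority_threshold modal-base frequency required to call a base;
#'   must lie in (0.25, 1].
#' @return Consensus string over `{A, C, G, T, n}`.
#' @export
derive_consensus <- function(matrix, majority_threshold = 0.75) {
  stopifnot(inherits(matrix, "motif_matrix"))
  if (majority_threshold <= 0.25 || majority_threshold > 1)
    stop("majority_threshold must lie in (0.25, 1]")
  p <- sweep(matrix$counts, 2, colSums(matrix$counts), "/")
  out <- vapply(seq_len(ncol(p)), function(j) {
    col <- p[, j]
    top <- max(col)
    if (top < majority_threshold || sum(col == top) > 1L) "n"
    else rownames(p)[which.max(col)]
  }, "")
  paste(out, collapse = "")
}
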