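#' The packaged PdhR binding-site catalogue
#'
#' Loads the transcription of the published table of 35 PdhR-binding sites on
#' the *E. coli* K-12 genome: peak position, screening intensities with and
#' without the effector pyruvate, context-type section, flanking genes with
#' transcription-direction arrows (and the host ORF for intragenic sites),
#' operon and function annotations, and — where printed — the 17-bp site
#' sequence with its conservation score and genome position.
#'
#' The first published intensity column is stored as `intensity_no_effector`
#' and the second as `intensity_effector` (see the file's header comments for
#' the rationale); absent values are `"-"` (motif positions `NA`).
#'
#' @param path fixture file; defaults to the copy installed with the package.
#' @return data.frame with 35 rows.
#' @export
#' @examples
#' tbl <- pdhr_table1()
#' table(tbl$type_printed)
pdhr_table1 <- function(path = system.file("extdata", "pdhr_table1_sites.tsv",
                                           package = "regulonscan")) {
  if (!nzchar(path) || !file.exists(path)) stop("fixture file not found")
  tbl <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = character())
  tbl$motif_position <- suppressWarnings(as.integer(
    ifelse(tbl$motif_position == "-", NA, tbl$motif_position)))
  tbl
}

#' Synthesize a minimal annotation from the fixture's gene arrows
#'
#' The published table prints, for every peak, its flanking genes and their
#' transcription directions (and, for intragenic sites, the host ORF), but
#' not their coordinates. This helper builds a synthetic [genome_annotation()]
#' that realises exactly those orientations: for each peak the left flank is
#' placed just before it, the right flank just after, and an intragenic
#' site's host ORF spans the peak. Only gene order and orientation relative
#' to each peak are real; the coordinates (offsets of a few hundred bp) are
#' synthetic, which is immaterial to context typing. The host ORF, whose
#' strand is not printed, inherits the left arrow's strand (classification
#' uses only containment).
#'
#' @param tbl data.frame from [pdhr_table1()].
#' @param genome_length genome size in bp (K-12 scale by default).
#' @return A [genome_annotation()].
#' @export
fixture_annotation <- function(tbl = pdhr_table1(), genome_length = 4641652) {
  dir2strand <- function(d) ifelse(d == ">", "+", "-")
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    r <- tbl[i, ]
    p <- r$peak_position
    host <- if (r$host_gene != "-") {
      data.frame(id = r$host_gene, start = p - 500L, end = p + 500L,
                 strand = dir2strand(r$left_dir),
                 product = NA_character_, operon = NA_character_)
    } else NULL
    pad <- if (is.null(host)) 0L else 500L   # keep flanks outside the host ORF
    left <- data.frame(id = r$left_gene, start = p - pad - 1100L,
                       end = p - pad - 200L, strand = dir2strand(r$left_dir),
                       product = r$left_function, operon = r$left_operon)
    right <- data.frame(id = r$right_gene, start = p + pad + 200L,
                        end = p + pad + 1100L, strand = dir2strand(r$right_dir),
                        product = r$right_function, operon = r$right_operon)
    rbind(left, host, right)
  })
  genome_annotation(do.call(rbind, rows), genome_length)
}

#' Re-validate the fixture's printed scores and casings
#'
#' Re-scores every fixture row that prints a site sequence against the box
#' and re-renders its match casing, then compares both to the printed
#' conservation value and sequence. Discrepancies are report content, not
#' errors.
#'
#' @details
#' On the packaged fixture, 27 of the 28 printed sequences reproduce both
#' score and casing byte-for-byte. The remaining row (peak 1150668,
#' `AcaTGGTctgACCgctt 8/14`) is internally inconsistent as published: its
#' trailing lowercase `tt` falls on box positions whose consensus base is
#' `T`, so rescoring the letters gives 10/14, while the printed count 8
#' equals the row's uppercase-letter count. The casing convention and the
#' printed score agree with each other, but the letter identities at the last
#' two positions contradict their mismatch (lowercase) rendering — evidently
#' a print defect in the source table. The row is transcribed verbatim and
#' reported as the single expected discrepancy.
#'
#' @param tbl data.frame in the [pdhr_table1()] layout (pass a modified copy
#'   to audit edits).
#' @param box the [palindrome_box()] to score against.
#' @return Object of class `fixture_validation`: data.frame with one row per
#'   printed sequence (`peak_position`, `printed_sequence`,
#'   `printed_conservation`, `computed_conservation`, `rendered_sequence`,
#'   `score_ok`, `casing_ok`), plus attribute `n_discrepancies`.
#' @export
validate_fixture <- function(tbl = pdhr_table1(), box = palindrome_box()) {
  scored <- tbl[tbl$site_sequence != "-", , drop = FALSE]
  rep <- data.frame(
    peak_position = scored$peak_position,
    printed_sequence = scored$site_sequence,
    printed_conservation = scored$conservation,
    stringsAsFactors = FALSE)
  rep$computed_conservation <- vapply(scored$site_sequence, function(s)
    score_against_box(toupper(s), box)$rendered, "")
  rep$rendered_sequence <- vapply(scored$site_sequence, function(s)
    render_match(toupper(s), box), "")
  rep$score_ok <- rep$computed_conservation == rep$printed_conservation
  rep$casing_ok <- rep$rendered_sequence == rep$printed_sequence
  rownames(rep) <- NULL
  structure(rep,
            n_discrepancies = sum(!rep$score_ok | !rep$casing_ok),
            class = c("fixture_validation", "data.frame"))
}

#' @export
print.fixture_validation <- function(x, ...) {
  nd <- attr(x, "n_discrepancies")
  cat(sprintf("fixture_validation: %d printed sequences, %d discrepanc%s\n",
              nrow(x), nd, if (nd == 1) "y" else "ies"))
  bad <- x[!x$score_ok | !x$casing_ok, , drop = FALSE]
  if (nrow(bad)) print.data.frame(bad)
  invisible(x)
}

#' Regulon expansion factor over previously known targets
#'
#' Ratio of screened binding sites to the previously catalogued target count
#' (nine PdhR targets in RegulonDB), rounded to one decimal: 35 sites over 9
#' known targets is a 3.9-fold expansion.
#'
#' @param n_sites number of binding sites retained by the screen.
#' @param n_known previously known target count.
#' @return The fold ratio rounded to one decimal.
#' @export
expansion_ratio <- function(n_sites, n_known = 9) {
  stopifnot(n_known > 0)
  round(n_sites / n_known, 1)
}
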