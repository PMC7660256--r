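#' Run the full regulon-expansion pipeline
#'
#' Orchestrates the dry-lab analysis end to end: obtain peaks (from a
#' pre-called peak table, or by calling them on an intensity track pair),
#' apply the intensity cutoff, type every site by genomic context, bound the
#' regulon size, score/scan the recognition box, build the count matrix and
#' derive a consensus, and assemble the report table.
#'
#' Exactly one peak source must be supplied: either `peak_table` (a
#' data.frame with `position`/`peak_position`, `intensity_no_effector`,
#' `intensity_effector` columns, e.g. [pdhr_table1()]), or `track` (plus
#' optionally `effector_track`). When a `genome` sequence is given, a window
#' of `window_size` bp centred on each peak is scanned for the best box
#' match; when the peak table already carries printed site sequences
#' (`site_sequence` column), those are used directly.
#'
#' @param annotation a [genome_annotation()].
#' @param peak_table pre-called peak table, or `NULL`.
#' @param track,effector_track [binding_track()]s, or `NULL`.
#' @param genome optional genome DNA string for motif scanning.
#' @param cutoff intensity cutoff (inclusive) on the no-effector screen.
#' @param min_separation minimum apex spacing for [call_peaks()].
#' @param box the [palindrome_box()].
#' @param window_size width of the scanned window centred on each peak.
#' @param reporting_floor minimum match count reported (see
#'   [assemble_site_table()]).
#' @param effector_threshold retained-fraction boundary for the sensitivity
#'   call.
#' @param majority_threshold for [derive_consensus()].
#' @param pseudocount for [build_matrix()].
#' @return Object of class `regulon_pipeline`: list with `peaks`, `sites`
#'   (typed sites), `site_table`, `estimate` (a `regulon_estimate`),
#'   `matrix` (a `motif_matrix`, or `NULL` if no sequence source), `consensus`
#'   (string or `NULL`), `effector` (per-site [effector_response()] rows) and
#'   `log` (character vector of run notes).
#' @export
#' @examples
#' tbl <- pdhr_table1()
#' res <- run_pipeline(fixture_annotation(tbl), peak_table = tbl)
#' res$estimate
run_pipeline <- function(annotation,
                         peak_table = NULL,
                         track = NULL,
                         effector_track = NULL,
                         genome = NULL,
                         cutoff = 500,
                         min_separation = 500,
                         box = palindrome_box(),
                         window_size = 500L,
                         reporting_floor = 7L,
                         effector_threshold = 0.5,
                         majority_threshold = 0.75,
                         pseudocount = 0) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (is.null(peak_table) == is.null(track))
    stop("supply exactly one peak source: peak_table or track")
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(track)) {
    if (length(track$values) * track$step < annotation$genome_length)
      stop("track covers ", length(track$values) * track$step,
           " bp but the annotation genome is ", annotation$genome_length, " bp")
    peaks <- pair_with_effector(call_peaks(track, cutoff, min_separation),
                                effector_track)
    note("called %d peaks at cutoff %g (min separation %g bp)",
         nrow(peaks), cutoff, min_separation)
  } else {
    peaks <- peak_table
    if ("peak_position" %in% names(peaks) && !"position" %in% names(peaks))
      peaks$position <- peaks$peak_position
    peaks <- filter_peak_table(peaks, cutoff)
    note("retained %d of %d peaks at cutoff %g",
         nrow(peaks), nrow(peak_table), cutoff)
  }
  if (nrow(annotation$features) == 0L)
    note("empty annotation: every site will lack flanking genes")

  n_warn <- 0L
  sites <- withCallingHandlers(
    classify_sites(peaks, annotation),
    warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  if (n_warn) note("%d boundary warning(s) during typing", n_warn)
  estimate <- estimate_regulon_size(sites)
  note("type counts A/B/C/D = %d/%d/%d/%d; regulon bounds [%d, %d]",
       estimate$n_typeA, estimate$n_typeB, estimate$n_typeC, estimate$n_typeD,
       estimate$min_targets, estimate$max_targets)

  matches <- NULL
  site_seqs <- character()
  if (!is.null(genome)) {
    matches <- lapply(peaks$position, function(p) {
      lo <- max(1L, as.integer(p) - window_size %/% 2L)
      hi <- min(nchar(genome), lo + window_size - 1L)
      scan_window(substr(genome, lo, hi), box, origin = lo)
    })
    site_seqs <- vapply(matches, function(m) m$site_sequence, "")
    note("scanned %d windows of %d bp", length(matches), window_size)
  } else if ("site_sequence" %in% names(peaks)) {
    printed <- peaks$site_sequence[peaks$site_sequence != "-"]
    site_seqs <- toupper(printed)
    matches <- lapply(seq_len(nrow(peaks)), function(i) {
      s <- peaks$site_sequence[i]
      if (s == "-") return(NULL)
      gp <- if (!is.null(peaks$motif_position)) peaks$motif_position[i]
            else NA_integer_
      structure(list(site_sequence = toupper(s),
                     score = score_against_box(toupper(s), box),
                     genome_position = gp,
                     offset = NA_integer_, strand = "+",
                     rendered_sequence = render_match(toupper(s), box)),
                class = "motif_match")
    })
    note("used %d printed site sequences", length(site_seqs))
  }
  mat <- NULL
  consensus <- NULL
  if (length(site_seqs)) {
    mat <- build_matrix(site_seqs, pseudocount)
    consensus <- derive_consensus(mat, majority_threshold)
    note("consensus at majority %.2f: %s", majority_threshold, consensus)
  }
  eff <- effector_response(peaks$intensity_no_effector,
                           peaks$intensity_effector,
                           threshold = effector_threshold)
  site_table <- assemble_site_table(
    sites,
    data.frame(position = peaks$position,
               intensity_no_effector = peaks$intensity_no_effector,
               intensity_effector = peaks$intensity_effector),
    matches, box, reporting_floor)
  structure(list(peaks = peaks, sites = sites, site_table = site_table,
                 estimate = estimate, matrix = mat, consensus = consensus,
                 effector = eff, n_warnings = n_warn, log = log),
            class = "regulon_pipeline")
}

#' @export
print.regulon_pipeline <- function(x, ...) {
  cat("regulon_pipeline result\n")
  cat(sprintf("  sites: %d\n", nrow(x$site_table)))
  print(x$estimate)
  if (!is.null(x$consensus)) cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' @export
summary.regulon_pipeline <- function(object, ...) {
  cat("Pipeline log:\n")
  cat(paste0("  - ", object$log, collapse = "\n"), "\n")
  print(object)
  invisible(object)
}
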