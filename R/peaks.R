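#' Construct a binding-intensity track
#'
#' A `binding_track` is a genome-wide, evenly spaced intensity profile, as
#' produced by hybridising an enriched fragment pool to a tiling array. Value
#' `i` covers the probe centred at `(i - 1) * step + 1`; intensities are
#' arbitrary fluorescence-ratio units, already normalised upstream, and must
#' be finite and non-negative.
#'
#' @param values numeric vector of per-probe intensities.
#' @param step probe spacing in bp.
#' @param condition free-text label (e.g. `"no_effector"`).
#' @return An object of class `binding_track`.
#' @export
binding_track <- function(values, step = 1L, condition = "") {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty track")
  if (any(!is.finite(values)) || any(values < 0))
    stop("track values must be finite and non-negative")
  step <- as.integer(step)
  stopifnot(step >= 1L)
  structure(list(values = values, step = step, condition = condition),
            class = "binding_track")
}

#' @export
print.binding_track <- function(x, ...) {
  cat(sprintf("binding_track%s: %d probes at %d bp step (%s bp), max %.1f\n",
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              length(x$values), x$step,
              format(length(x$values) * x$step, big.mark = ","),
              max(x$values)))
  invisible(x)
}

#' Genome position of track index
#' @noRd
track_position <- function(track, idx) (idx - 1L) * track$step + 1L

#' Read a binding track from bedGraph or fixed-step WIG
#'
#' Parsed via \pkg{rtracklayer}; the covered intervals are rasterised onto an
#' even `step` grid (the track's native resolution if `step` is `NULL`,
#' inferred as the most common interval width). Uncovered positions get
#' intensity 0.
#'
#' @param path `.bedGraph`/`.bedgraph` or `.wig` file.
#' @param genome_length genome size in bp (grid extent).
#' @param step grid spacing in bp, or `NULL` to infer.
#' @param condition label stored on the track.
#' @return A [binding_track].
#' @export
read_track <- function(path, genome_length, step = NULL, condition = "") {
  if (!file.exists(path)) stop("track file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext, bedgraph = "bedGraph", bg = "bedGraph", wig = "wig",
                stop("unsupported track format: .", ext))
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr)
  if (nrow(df) == 0L) stop("empty track: ", path)
  if (is.null(step)) {
    w <- df$end - df$start + 1L
    step <- as.integer(names(sort(table(w), decreasing = TRUE))[1])
  }
  step <- as.integer(step)
  n <- ceiling(genome_length / step)
  values <- numeric(n)
  idx <- pmin(n, pmax(1L, floor((df$start - 1L) / step) + 1L))
  values[idx] <- df$score
  binding_track(values, step = step, condition = condition)
}

#' Write a binding track as bedGraph
#'
#' @param track a [binding_track].
#' @param path output file.
#' @param seqname chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, seqname = "genome") {
  stopifnot(inherits(track, "binding_track"))
  n <- length(track$values)
  start0 <- (seq_len(n) - 1L) * track$step        # bedGraph is 0-based half-open
  lines <- sprintf("%s\t%d\t%d\t%s", seqname, start0, start0 + track$step,
                   formatC(track$values, format = "g", digits = 10))
  writeLines(lines, path)
  invisible(path)
}

#' Call binding peaks from an intensity track
#'
#' A peak is a local intensity maximum at or above `cutoff`. On plateaus the
#' leftmost probe is the apex. Maxima closer than `min_separation` are merged,
#' keeping the higher (ties resolved to the leftmost). The published screen
#' used a hard cutoff of 500 intensity units on the no-effector track.
#'
#' @param track a [binding_track].
#' @param cutoff minimum apex intensity (inclusive); must be positive.
#' @param min_separation minimum apex spacing in bp.
#' @return data.frame with columns `position` (1-based apex bp) and
#'   `intensity`, sorted by position.
#' @export
#' @examples
#' tr <- binding_track(c(1, 5, 900, 5, 1, 700, 2), step = 100)
#' call_peaks(tr, cutoff = 500, min_separation = 100)
call_peaks <- function(track, cutoff = 500, min_separation = 500) {
  stopifnot(inherits(track, "binding_track"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number")
  if (min_separation < 0) stop("min_separation must be >= 0")
  v <- track$values
  n <- length(v)
  # local maximum: >= both neighbours and, on a plateau, the leftmost probe
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  is_max <- v >= cutoff & v >= right & v > left
  idx <- which(is_max)
  if (length(idx) == 0L)
    return(data.frame(position = integer(), intensity = numeric()))
  # merge close maxima: repeatedly keep the highest remaining (tie -> leftmost)
  ord <- order(-v[idx], idx)
  cand <- idx[ord]
  kept <- integer()
  for (i in cand) {
    if (!length(kept) ||
        all(abs(track_position(track, i) - track_position(track, kept)) >=
            min_separation))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(position = track_position(track, kept), intensity = v[kept])
}

#' Pair peaks with a second (effector) screen
#'
#' Reads off the effector-track intensity at each called apex, so that paired
#' screens with and without the effector ligand can be compared per site.
#'
#' @param peaks data.frame from [call_peaks()] on the no-effector track.
#' @param effector_track a [binding_track] for the + effector screen, or
#'   `NULL` (effector intensities set `NA`).
#' @return data.frame with columns `position`, `intensity_no_effector`,
#'   `intensity_effector`.
#' @export
pair_with_effector <- function(peaks, effector_track = NULL) {
  out <- data.frame(position = peaks$position,
                    intensity_no_effector = peaks$intensity,
                    intensity_effector = NA_real_)
  if (!is.null(effector_track)) {
    stopifnot(inherits(effector_track, "binding_track"))
    idx <- pmin(length(effector_track$values),
                pmax(1L, round((out$position - 1L) / effector_track$step) + 1L))
    out$intensity_effector <- effector_track$values[idx]
  }
  out
}

#' Filter a peak table by the no-effector intensity cutoff
#'
#' @param peaks data.frame with an `intensity_no_effector` column.
#' @param cutoff minimum intensity (inclusive).
#' @return The retained rows, order preserved.
#' @export
filter_peak_table <- function(peaks, cutoff = 500) {
  if (!"intensity_no_effector" %in% names(peaks))
    stop("peak table lacks an intensity_no_effector column")
  peaks[!is.na(peaks$intensity_no_effector) &
          peaks$intensity_no_effector >= cutoff, , drop = FALSE]
}

#' Effector sensitivity of a binding site
#'
#' The retained fraction is the ratio of the + effector to the no-effector
#' intensity (with an optional shared pseudocount); a site is called sensitive
#' when the fraction falls below `threshold`. For the pyruvate-sensing
#' repressor this captures the loss of DNA binding on effector binding.
#'
#' @param intensity_no_effector,intensity_effector apex intensities; vectors
#'   recycle. A missing (`NA`) effector intensity yields `NA` results rather
#'   than an error.
#' @param pseudocount added to both intensities before division.
#' @param threshold retained-fraction boundary for the `sensitive` call.
#' @return data.frame with columns `retained_fraction` and `sensitive`.
#' @export
#' @examples
#' effector_response(3469, 383)   # ascB site: ~0.11, sensitive
effector_response <- function(intensity_no_effector, intensity_effector,
                              pseudocount = 0, threshold = 0.5) {
  stopifnot(pseudocount >= 0)
  rf <- (intensity_effector + pseudocount) /
    (intensity_no_effector + pseudocount)
  data.frame(retained_fraction = rf, sensitive = rf < threshold)
}
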