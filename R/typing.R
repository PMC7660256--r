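#' Classify a binding site by genomic context
#'
#' Assigns one of four context types to a peak position:
#' \describe{
#'   \item{A}{intergenic, upstream of both flanking genes — a divergent
#'     spacer (left gene on the minus strand, right gene on the plus strand);
#'     both flanks are candidate regulatory targets.}
#'   \item{B}{intergenic, upstream of exactly one flanking gene — a tandem
#'     spacer; that gene is the candidate target.}
#'   \item{C}{intergenic, upstream of neither flank — a convergent spacer
#'     (downstream of both transcription units); no candidate target.}
#'   \item{D}{inside an open reading frame; the host gene is recorded but
#'     contributes no candidate target.}
#' }
#' On a linear genome a peak missing one flank is classified from the
#' existing side only, with a warning.
#'
#' @param position 1-based peak (apex) position.
#' @param annotation a [genome_annotation()].
#' @return Object of class `typed_site`: list with `position`, `site_type`
#'   (`"A"`, `"B"`, `"C"` or `"D"`), `context` (the [context_at()] result) and
#'   `regulated_genes` (data.frame of 0-2 genes the site is upstream of).
#' @export
#' @examples
#' ann <- genome_annotation(
#'   data.frame(id = c("aroP", "pdhR"), start = c(100, 600),
#'              end = c(400, 900), strand = c("-", "+")), 1000)
#' classify_site(500, ann)$site_type  # divergent spacer -> "A"
classify_site <- function(position, annotation) {
  ctx <- context_at(annotation, position)
  f0 <- annotation$features[0, , drop = FALSE]
  if (ctx$kind == "intragenic") {
    site <- list(position = ctx$position, site_type = "D", context = ctx,
                 regulated_genes = f0)
    class(site) <- "typed_site"
    return(site)
  }
  flanks <- list(ctx$left_gene, ctx$right_gene)
  present <- !vapply(flanks, is.null, TRUE)
  if (!all(present))
    warning("no flanking gene on ", if (!present[1]) "left" else "right",
            " side of position ", ctx$position,
            "; classified from the existing side only")
  up <- vapply(flanks, function(g) {
    !is.null(g) && upstream_of(g, ctx$position)
  }, TRUE)
  regulated <- do.call(rbind, flanks[up])
  if (is.null(regulated)) regulated <- f0
  site_type <- if (sum(up) == 2L) "A" else if (sum(up) == 1L) "B" else "C"
  site <- list(position = ctx$position, site_type = site_type, context = ctx,
               regulated_genes = regulated)
  class(site) <- "typed_site"
  site
}

#' @export
print.typed_site <- function(x, ...) {
  reg <- if (nrow(x$regulated_genes)) paste(x$regulated_genes$id, collapse = ", ")
         else "(none)"
  cat(sprintf("typed_site: position %d, type %s, regulated: %s\n",
              x$position, x$site_type, reg))
  invisible(x)
}

#' Classify every peak in a table
#'
#' @param peaks data.frame with a `position` column (other columns carried
#'   through, e.g. intensities).
#' @param annotation a [genome_annotation()].
#' @return List of [classify_site()] results, one per row, in input order.
#' @export
classify_sites <- function(peaks, annotation) {
  lapply(peaks$position, classify_site, annotation = annotation)
}

#' Bound the regulon size from typed sites
#'
#' Counts sites per type and bounds the number of regulated transcription
#' units: each intergenic upstream site (type A or B) contributes at least
#' one target, and a divergent (type A) site may regulate both of its
#' flanking units, so
#' `min = n_A + n_B` and `max = 2 * n_A + n_B`. Type-C and type-D sites are
#' counted but contribute to neither bound.
#'
#' @param sites list of `typed_site` objects (from [classify_sites()]), or a
#'   character vector of types `"A"/"B"/"C"/"D"`.
#' @return Object of class `regulon_estimate`: list with `n_typeA`,
#'   `n_typeB`, `n_typeC`, `n_typeD`, `min_targets`, `max_targets`.
#' @export
#' @examples
#' estimate_regulon_size(c(rep("A", 7), rep("B", 9), rep("D", 19)))
estimate_regulon_size <- function(sites) {
  types <- if (is.character(sites)) sites
           else vapply(sites, function(s) s$site_type, "")
  if (!all(types %in% c("A", "B", "C", "D")))
    stop("site types must be A, B, C or D")
  n <- vapply(c(A = "A", B = "B", C = "C", D = "D"),
              function(t) sum(types == t), 0L)
  structure(list(n_typeA = n[["A"]], n_typeB = n[["B"]],
                 n_typeC = n[["C"]], n_typeD = n[["D"]],
                 min_targets = n[["A"]] + n[["B"]],
                 max_targets = 2L * n[["A"]] + n[["B"]]),
            class = "regulon_estimate")
}

#' @export
print.regulon_estimate <- function(x, ...) {
  cat(sprintf("regulon_estimate: %d type-A, %d type-B, %d type-C, %d type-D sites\n",
              x$n_typeA, x$n_typeB, x$n_typeC, x$n_typeD))
  cat(sprintf("  predicted regulatory targets: between %d and %d transcription units\n",
              x$min_targets, x$max_targets))
  invisible(x)
}

#' Assemble the binding-site report table
#'
#' Joins typed sites with their motif matches into one row per site, in the
#' layout of the published catalogue: peak position, both intensities,
#' context type, flanking genes with transcription-direction arrows, the
#' case-rendered site sequence, its conservation as `"n/14"`, and the motif's
#' genome position. Sites without a motif match at or above
#' `reporting_floor` print `-` in the motif columns.
#'
#' @param sites list of `typed_site` objects.
#' @param peaks data.frame aligned with `sites`, with columns `position`,
#'   `intensity_no_effector`, `intensity_effector` (peak identities must be
#'   unique).
#' @param matches optional list aligned with `sites`; each element a
#'   `motif_match` (from [scan_window()]) or `NULL`.
#' @param box the [palindrome_box()] the matches were scored against.
#' @param reporting_floor minimum match count for a motif to be reported; the
#'   default 7 corresponds to the weakest published score, 7/14.
#' @return data.frame with one row per site.
#' @export
assemble_site_table <- function(sites, peaks, matches = NULL,
                                box = palindrome_box(), reporting_floor = 7L) {
  if (anyDuplicated(peaks$position))
    stop("duplicate peak position(s): ",
         paste(unique(peaks$position[duplicated(peaks$position)]),
               collapse = ", "))
  stopifnot(length(sites) == nrow(peaks))
  if (!is.null(matches)) stopifnot(length(matches) == length(sites))
  if (length(sites) == 0L)
    return(data.frame(peak_position = integer(),
                      intensity_no_effector = numeric(),
                      intensity_effector = numeric(),
                      site_type = character(), left_gene = character(),
                      left_dir = character(), host_gene = character(),
                      right_dir = character(), right_gene = character(),
                      regulated_genes = character(),
                      site_sequence = character(), conservation = character(),
                      motif_position = integer(), stringsAsFactors = FALSE))
  rows <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    ctx <- s$context
    gene_or <- function(g, field) if (is.null(g)) "-" else as.character(g[[field]])
    arrow <- function(g) if (is.null(g)) "-" else if (g$strand == "+") ">" else "<"
    m <- if (!is.null(matches)) matches[[i]] else NULL
    has_motif <- !is.null(m) && m$score$matches >= reporting_floor
    data.frame(
      peak_position = s$position,
      intensity_no_effector = peaks$intensity_no_effector[i],
      intensity_effector = peaks$intensity_effector[i],
      site_type = s$site_type,
      left_gene = gene_or(ctx$left_gene, "id"),
      left_dir = arrow(ctx$left_gene),
      host_gene = gene_or(ctx$host_gene, "id"),
      right_dir = arrow(ctx$right_gene),
      right_gene = gene_or(ctx$right_gene, "id"),
      regulated_genes = if (nrow(s$regulated_genes))
        paste(s$regulated_genes$id, collapse = ",") else "-",
      site_sequence = if (has_motif) m$rendered_sequence else "-",
      conservation = if (has_motif) m$score$rendered else "-",
      motif_position = if (has_motif) m$genome_position else NA_integer_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a site report table as TSV
#'
#' @param table data.frame from [assemble_site_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "-")
  invisible(path)
}
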