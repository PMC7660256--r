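#' Construct a genome annotation
#'
#' A `genome_annotation` holds the coding-region coordinates that define
#' "upstream" and "inside an ORF" for binding-site typing. Gene bodies are CDS
#' extents; promoters and UTRs are not modelled, so "upstream of a gene" means
#' the intergenic spacer on its 5' side.
#'
#' @param features data.frame with columns `id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), and optionally `product` and `operon`. Coordinates are
#'   1-based inclusive with `start <= end`. Overlapping genes are permitted
#'   and preserved.
#' @param genome_length genome size in bp; all features must fit in
#'   `[1, genome_length]`.
#' @param circular if `TRUE`, flanking-gene searches wrap across the origin.
#' @return An object of class `genome_annotation`: a list with `features`
#'   (sorted by `start`), `genome_length` and `circular`.
#' @seealso [load_annotation()], [context_at()], [upstream_of()]
#' @export
#' @examples
#' ann <- genome_annotation(
#'   data.frame(id = c("g1", "g2"), start = c(100, 600), end = c(400, 900),
#'              strand = c("+", "-")),
#'   genome_length = 1000)
#' context_at(ann, 500)$kind
genome_annotation <- function(features, genome_length, circular = FALSE) {
  stopifnot(is.numeric(genome_length), length(genome_length) == 1L,
            genome_length >= 1)
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(id = character(), start = integer(),
                           end = integer(), strand = character(),
                           product = character(), operon = character(),
                           stringsAsFactors = FALSE)
  }
  req <- c("id", "start", "end", "strand")
  missing_cols <- setdiff(req, names(features))
  if (length(missing_cols))
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"product" %in% names(features)) features$product <- NA_character_
  if (!"operon" %in% names(features)) features$operon <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.character(features$strand)
  bad <- which(features$start < 1 | features$end > genome_length)
  if (length(bad))
    stop("feature(s) outside [1, genome_length]: ",
         paste(features$id[bad], collapse = ", "))
  bad <- which(features$end < features$start)
  if (length(bad))
    stop("feature(s) with end < start: ", paste(features$id[bad], collapse = ", "))
  if (!all(features$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(features = features,
                 genome_length = as.integer(genome_length),
                 circular = isTRUE(circular)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d features on a %s genome of %s bp\n",
              nrow(x$features), if (x$circular) "circular" else "linear",
              format(x$genome_length, big.mark = ",")))
  if (nrow(x$features)) {
    print(head(x$features[, c("id", "start", "end", "strand")], 6))
    if (nrow(x$features) > 6) cat("...\n")
  }
  invisible(x)
}

#' Load a genome annotation from GFF3 or BED
#'
#' Reads gene features via \pkg{rtracklayer} (GFF3 read natively; BED start
#' coordinates converted to 1-based on input) and returns a sorted
#' [genome_annotation]. For GFF3, only records whose `type` is listed in
#' `feature_types` are kept, and the gene name is taken from the `Name`
#' attribute, falling back to `ID`. For BED, the name and strand columns are
#' used directly.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED (`.bed`) file.
#' @param genome_length genome size in bp.
#' @param feature_types GFF3 `type` values that count as genes.
#' @param circular passed to [genome_annotation()].
#' @return A [genome_annotation].
#' @export
load_annotation <- function(path, genome_length,
                            feature_types = c("gene", "CDS"),
                            circular = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fmt <- switch(ext, gff = "gff3", gff3 = "gff3", bed = "bed",
                stop("unsupported annotation format: .", ext,
                     " (expected GFF3 or BED)"))
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr)
  if (fmt == "gff3" && nrow(df)) {
    df <- df[as.character(df$type) %in% feature_types, , drop = FALSE]
    id <- if ("Name" %in% names(df)) as.character(df$Name) else NA_character_
    alt <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
    id <- ifelse(is.na(id) | id == "", alt, id)
  } else {
    id <- if ("name" %in% names(df)) as.character(df$name) else NA_character_
  }
  if (nrow(df) == 0L)
    return(genome_annotation(NULL, genome_length, circular))
  strand <- as.character(df$strand)
  if (any(strand == "*"))
    stop("unstranded feature(s) in ", path, "; gene strand is required")
  feats <- data.frame(id = id, start = df$start, end = df$end,
                      strand = strand, stringsAsFactors = FALSE)
  feats$product <- if ("product" %in% names(df)) as.character(df$product) else NA_character_
  feats$operon <- if ("operon" %in% names(df)) as.character(df$operon) else NA_character_
  genome_annotation(feats, genome_length, circular)
}

#' Write a genome annotation to GFF3
#'
#' @param annotation a [genome_annotation].
#' @param path output file (`.gff3`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  f <- annotation$features
  gr <- GenomicRanges::GRanges(
    seqnames = "genome",
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand,
    seqlengths = c(genome = annotation$genome_length))
  gr$type <- rep("gene", nrow(f))
  gr$ID <- f$id
  gr$Name <- f$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Genomic context of a position
#'
#' Classifies a single genome position as intragenic (inside some gene body)
#' or intergenic, and finds the nearest flanking genes. When several genes
#' overlap the position, the one with the smallest start is the host. On a
#' circular genome the flanking-gene search wraps across the origin; on a
#' linear genome a missing flank is returned as `NULL`.
#'
#' @param annotation a [genome_annotation].
#' @param position 1-based genome coordinate.
#' @return A list of class `genomic_context` with elements `kind`
#'   (`"intragenic"` or `"intergenic"`), `host_gene` (one-row data.frame or
#'   `NULL`), `left_gene`, `right_gene` (nearest flanks, or `NULL`) and
#'   `position`.
#' @export
context_at <- function(annotation, position) {
  stopifnot(inherits(annotation, "genome_annotation"))
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > annotation$genome_length)
    stop("position out of range [1, ", annotation$genome_length, "]: ", position)
  f <- annotation$features
  hit <- which(f$start <= position & f$end >= position)
  if (length(hit)) {
    host <- f[hit[which.min(f$start[hit])], , drop = FALSE]
    # neighbours outside the host body, kept for reporting only
    li <- which(f$end < host$start)
    ri <- which(f$start > host$end)
    ctx <- list(kind = "intragenic", host_gene = host,
                left_gene = if (length(li)) f[li[which.max(f$end[li])], , drop = FALSE] else NULL,
                right_gene = if (length(ri)) f[ri[which.min(f$start[ri])], , drop = FALSE] else NULL,
                position = position)
    class(ctx) <- "genomic_context"
    return(ctx)
  }
  left_idx <- which(f$end < position)
  right_idx <- which(f$start > position)
  left <- if (length(left_idx)) {
    cand <- left_idx[which.max(f$end[left_idx])]
    f[cand, , drop = FALSE]
  } else NULL
  right <- if (length(right_idx)) {
    cand <- right_idx[which.min(f$start[right_idx])]
    f[cand, , drop = FALSE]
  } else NULL
  if (annotation$circular && nrow(f)) {
    if (is.null(left)) left <- f[which.max(f$end), , drop = FALSE]
    if (is.null(right)) right <- f[which.min(f$start), , drop = FALSE]
  }
  ctx <- list(kind = "intergenic", host_gene = NULL,
              left_gene = left, right_gene = right, position = position)
  class(ctx) <- "genomic_context"
  ctx
}

#' @export
print.genomic_context <- function(x, ...) {
  if (x$kind == "intragenic") {
    cat(sprintf("position %d: intragenic, inside %s [%d-%d](%s)\n",
                x$position, x$host_gene$id, x$host_gene$start,
                x$host_gene$end, x$host_gene$strand))
  } else {
    lg <- if (is.null(x$left_gene)) "(none)" else x$left_gene$id
    rg <- if (is.null(x$right_gene)) "(none)" else x$right_gene$id
    cat(sprintf("position %d: intergenic, between %s and %s\n",
                x$position, lg, rg))
  }
  invisible(x)
}

#' Is a position upstream of a gene?
#'
#' Upstream means on the 5' side of the coding region: before `start` for a
#' plus-strand gene, after `end` for a minus-strand gene. The position must
#' lie outside the gene body.
#'
#' @param gene one-row data.frame with `start`, `end`, `strand` (as stored in
#'   a [genome_annotation]).
#' @param position 1-based genome coordinate outside the gene body.
#' @return `TRUE` or `FALSE`.
#' @export
upstream_of <- function(gene, position) {
  position <- as.integer(position)
  if (position >= gene$start && position <= gene$end)
    stop("position ", position, " lies inside gene ", gene$id,
         " [", gene$start, "-", gene$end, "]")
  if (gene$strand == "+") position < gene$start else position > gene$end
}
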