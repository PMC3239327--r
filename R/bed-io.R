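# BED3/BED5 readers and writers.  Tab-separated, no header; "track",
# "browser" and "#" lines are skipped.  Validation is positional: a line
# that fails the coordinate contract is reported by its line number.

parse_bed_lines <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a BED3/BED5 file as a region set
#'
#' Columns: chrom, start, end, optional name and score.  Coordinates are
#' BED-style 0-based half-open.  Lines with non-integer coordinates or
#' `start >= end` raise an error naming the offending line.
#'
#' @param path path to a BED file.
#' @param label track label stored in `metadata(gr)$label` (defaults to the
#'   file name without extension).
#' @param genome optional genome for clamping/validation.
#' @return GRanges sorted by (chrom, start, end); `name`/`score` metadata
#'   columns are retained when present.
#' @export
read_bed <- function(path, label = NULL, genome = NULL) {
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  parsed <- parse_bed_lines(path)
  if (length(parsed$lines) == 0L) {
    gr <- GRanges()
    S4Vectors::metadata(gr)$label <- label
    return(gr)
  }
  fields <- strsplit(parsed$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", parsed$lineno[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns in ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("line ", parsed$lineno[bad[1L]], ": non-integer coordinates in ", path)
  bad <- which(s >= e | s < 0L)
  if (length(bad))
    stop("line ", parsed$lineno[bad[1L]],
         ": start must satisfy 0 <= start < end in ", path)
  gr <- granges0(chrom, s, e, genome = genome)
  if (all(nf >= 4L)) mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L))
    mcols(gr)$score <- as.numeric(vapply(fields, `[[`, "", 5L))
  gr <- sort_regions(gr)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED3, or BED5 when `name`/`score` metadata columns are present
#' (a missing score column is written as 0).
#'
#' @param gr GRanges to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start0(gr), end = end0(gr))
  mc <- mcols(gr)
  if ("name" %in% colnames(mc)) {
    d$name <- mc$name
    d$score <- if ("score" %in% colnames(mc)) mc$score else 0
  }
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-factor peak file (BED5)
#'
#' The 4th column (or, when absent, `factor`) names the transcription
#' factor; the 5th column is the ChIP tag intensity (0 when absent).
#'
#' @param path BED file of peaks for one factor dataset.
#' @param factor factor name; defaults to the file name without extension.
#' @param genome optional genome.
#' @return GRanges with metadata columns `factor`, `intensity`, `source_id`.
#' @export
read_peaks <- function(path, factor = NULL, genome = NULL) {
  if (is.null(factor)) factor <- sub("\\.[^.]*$", "", basename(path))
  gr <- read_bed(path, label = factor, genome = genome)
  mc <- mcols(gr)
  fac <- if ("name" %in% colnames(mc)) mc$name else rep(factor, length(gr))
  intensity <- if ("score" %in% colnames(mc)) mc$score else rep(0, length(gr))
  peaks(granges(gr), factor = fac, intensity = intensity,
        source_id = paste0(factor, "_", seq_along(gr)))
}

#' Construct a peak GRanges
#'
#' @param gr GRanges of peak intervals.
#' @param factor factor name per peak (nonempty).
#' @param intensity nonnegative tag intensity per peak.
#' @param source_id stable identifier per peak (generated when NULL).
#' @return GRanges with the peak metadata columns.
#' @export
peaks <- function(gr, factor, intensity = 0, source_id = NULL) {
  factor <- rep_len(as.character(factor), length(gr))
  intensity <- rep_len(as.numeric(intensity), length(gr))
  if (any(!nzchar(factor))) stop("factor names must be nonempty")
  if (any(intensity < 0)) stop("intensities must be >= 0")
  if (is.null(source_id)) source_id <- sprintf("peak_%d", seq_along(gr))
  mcols(gr) <- DataFrame(factor = factor, intensity = intensity,
                         source_id = as.character(source_id))
  gr
}
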