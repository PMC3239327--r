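# Interval algebra on GRanges.  All operations are strand-agnostic: tracks
# of peaks, marks and open-chromatin regions are unstranded.

#' Merge overlapping (and book-ended) intervals
#'
#' Condenses a region set into pairwise-disjoint intervals covering the
#' same bases; intervals that touch end-to-start are merged too.
#'
#' @param gr GRanges.
#' @return merged GRanges, sorted.
#' @export
merge_overlapping <- function(gr) {
  reduce(granges(gr), ignore.strand = TRUE)
}

#' Merge intervals within an edge-to-edge gap
#'
#' Intervals on the same chromosome whose edge-to-edge distance
#' (`next start - previous end`, 0-based) is at most `gap` are merged
#' transitively.  `gap = 0` merges only overlapping/touching intervals.
#'
#' @param gr GRanges.
#' @param gap maximum merge distance in bp (>= 0).
#' @return merged GRanges.
#' @export
merge_within_gap <- function(gr, gap) {
  if (gap < 0) stop("gap must be >= 0")
  reduce(granges(gr), min.gapwidth = gap + 1L, ignore.strand = TRUE)
}

#' Split intervals to a maximum length
#'
#' Each interval is cut left-to-right into full `max_len` pieces with the
#' remainder last, so per-interval pieces concatenate back exactly.  Used
#' to put broad histone-modification domains on a comparable footing
#' (default elsewhere: 5,000 bp).
#'
#' @param gr GRanges.
#' @param max_len maximum piece length in bp (> 0).
#' @return GRanges of pieces, input order preserved.
#' @export
split_to_max_length <- function(gr, max_len) {
  if (max_len <= 0) stop("max_len must be > 0")
  max_len <- as.integer(max_len)
  w <- width(gr)
  npieces <- ceiling(w / max_len)
  idx <- rep(seq_along(gr), npieces)
  offset <- unlist(lapply(npieces, function(k) seq_len(k) - 1L), use.names = FALSE)
  if (length(idx) == 0L) return(granges(gr))
  s0 <- start0(gr)[idx] + offset * max_len
  e0 <- pmin(s0 + max_len, end0(gr)[idx])
  GRanges(seqnames(gr)[idx], IRanges(s0 + 1L, e0), seqinfo = seqinfo(gr))
}

#' Fraction of query intervals overlapping a subject set
#'
#' Overlap means at least one shared base.  Returns 0 for an empty query.
#'
#' @param query,subject GRanges.
#' @return fraction in [0, 1].
#' @export
overlap_fraction <- function(query, subject) {
  if (length(query) == 0L) return(0)
  mean(countOverlaps(query, subject, ignore.strand = TRUE) > 0L)
}
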