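# Transcript vs enhancer classification from chromatin domains, and
# cluster/mark overlap summaries.
#
# A cluster is "transcript" when it overlaps H3K36me3 or Pol II (or,
# independently, Pol III), or when it overlaps an H3K4me3 domain that is
# itself linked to H3K36me3 or Pol II; an isolated H3K4me3 domain does not
# make a transcript call.  Everything else is "enhancer".  Classification
# consults full-length domains; overlap statistics elsewhere use domains
# split to a maximum length (5,000 bp) so broad and narrow marks are
# comparable.

#' Build a mark library
#'
#' Stores each chromatin track twice: the full-length domains (used only
#' for transcript-cluster identification) and the domains split to
#' `max_len` pieces (used for all overlap statistics).
#'
#' @param tracks named list of GRanges, one per mark
#'   (e.g. "H3K4me1", "H3K36me3", "PolII", "OCR").
#' @param max_len maximum split-piece length in bp.
#' @return object of class `mark_library` with elements `full`, `split`,
#'   `max_len`.
#' @export
mark_library <- function(tracks, max_len = 5000L) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("tracks must be a named list of GRanges")
  full <- lapply(tracks, merge_overlapping)
  structure(list(full = full,
                 split = lapply(full, split_to_max_length, max_len = max_len),
                 max_len = as.integer(max_len)),
            class = "mark_library")
}

#' @export
print.mark_library <- function(x, ...) {
  cat("mark_library:", length(x$full), "tracks (split at", x$max_len, "bp)\n")
  for (nm in names(x$full))
    cat("  ", nm, ": ", length(x$full[[nm]]), " domains\n", sep = "")
  invisible(x)
}

#' Classify clusters as transcript or enhancer
#'
#' Rules, applied in order for provenance (the class itself is
#' order-independent): overlap with H3K36me3; overlap with Pol II; overlap
#' with an H3K4me3 domain linked (overlapping) to H3K36me3 or Pol II;
#' overlap with Pol III when present.  Clusters whose member factors all
#' fall in `exclude_factors` (architectural factors such as CTCF/Rad21)
#' are dropped from classification; mixed clusters keep all their peaks.
#'
#' @param cs a `cluster_set` from [build_clusters()].
#' @param marks a [mark_library()]; must contain full-length "H3K36me3",
#'   "H3K4me3" and "PolII" tracks ("PolIII" optional).
#' @param exclude_factors factors whose pure clusters are dropped.
#' @return data.frame with one row per classified cluster: `cluster`
#'   (index into `cs$clusters`), `class` ("transcript"/"enhancer") and
#'   `provenance` ("H3K36me3", "PolII", "H3K4me3-linked", "PolIII",
#'   "none").
#' @export
classify_clusters <- function(cs, marks,
                              exclude_factors = c("CTCF", "Rad21")) {
  need <- c("H3K36me3", "H3K4me3", "PolII")
  missing <- setdiff(need, names(marks$full))
  if (length(missing))
    stop("mark library lacks required track(s): ",
         paste(missing, collapse = ", "))
  fsets <- cluster_factor_sets(cs)
  keep <- which(!vapply(fsets, function(f) all(f %in% exclude_factors),
                        TRUE))
  regions <- cs$clusters[keep]
  k36 <- marks$full$H3K36me3
  pol2 <- marks$full$PolII
  k4 <- marks$full$H3K4me3
  # H3K4me3 domains linked to transcription evidence
  linked <- k4[countOverlaps(k4, k36, ignore.strand = TRUE) +
                 countOverlaps(k4, pol2, ignore.strand = TRUE) > 0L]
  hit <- function(track) countOverlaps(regions, track,
                                       ignore.strand = TRUE) > 0L
  provenance <- rep("none", length(regions))
  provenance[hit(linked)] <- "H3K4me3-linked"
  if (!is.null(marks$full$PolIII))
    provenance[provenance == "none" & hit(marks$full$PolIII)] <- "PolIII"
  provenance[hit(pol2)] <- "PolII"
  provenance[hit(k36)] <- "H3K36me3"
  data.frame(cluster = keep,
             class = ifelse(provenance == "none", "enhancer", "transcript"),
             provenance = provenance)
}

#' Cross-tabulate cluster class against annotation and expression
#'
#' @param classes data.frame from [classify_clusters()].
#' @param contexts data.frame from [assign_gene_context()] over the same
#'   cluster GRanges (row i = cluster i).
#' @param expr_classes named vector from [classify_expression()].
#' @return list of two tables: `by_annotation` (class x inside/outside
#'   annotated genes and promoters) and `by_expression` (class x
#'   expression class of the assigned gene, clusters with a gene only).
#' @export
cross_tabulate <- function(classes, contexts, expr_classes) {
  ctx <- contexts[classes$cluster, , drop = FALSE]
  inside <- factor(ifelse(ctx$context == "intergenic", "outside", "inside"),
                   levels = c("inside", "outside"))
  cls <- factor(classes$class, levels = c("transcript", "enhancer"))
  by_annotation <- table(class = cls, location = inside)
  has_gene <- !is.na(ctx$gene_id)
  expr <- factor(unname(expr_classes[ctx$gene_id[has_gene]]),
                 levels = c("high", "medium_low", "zero"))
  by_expression <- table(class = cls[has_gene], expression = expr)
  list(by_annotation = by_annotation, by_expression = by_expression)
}

#' Enhancer-marker overlap fractions
#'
#' Fraction of (typically intergenic) enhancer clusters overlapping each
#' candidate enhancer marker, using split domains.
#'
#' @param regions GRanges of enhancer cluster regions.
#' @param marks a [mark_library()].
#' @param markers marker names to report (default: all tracks).
#' @return named numeric vector of overlap fractions.
#' @export
enhancer_marker_overlap <- function(regions, marks,
                                    markers = names(marks$split)) {
  vapply(markers, function(m) {
    if (is.null(marks$split[[m]])) stop("no such mark track: ", m)
    overlap_fraction(regions, marks$split[[m]])
  }, numeric(1))
}

#' Redundancy ratio of a chromatin mark
#'
#' Total mark regions divided by the mark regions occupied by (overlapping)
#' at least one cluster; 1 means every marked region is bound, larger
#' values mean the mark is redundant with respect to factor binding.
#' Returns 0 when no region is occupied.
#'
#' @param mark merged GRanges of mark regions (split or full).
#' @param regions GRanges of cluster regions.
#' @return ratio >= 1, or 0 when no mark region is occupied.
#' @export
redundancy_ratio <- function(mark, regions) {
  n <- length(mark)
  if (n == 0L) return(0)
  occupied <- sum(countOverlaps(mark, regions, ignore.strand = TRUE) > 0L)
  if (occupied == 0L) return(0)
  n / occupied
}
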