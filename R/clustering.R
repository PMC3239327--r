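# Transcription factor cluster construction and the shuffle null.
#
# Each peak is extended to a fixed total length (default 2,000 bp, the
# usual promoter-window scale) about its midpoint; peaks whose extended
# intervals overlap belong to the same cluster.  Regions holding more than
# one peak are "clusters", the rest "singletons".  The null model shuffles
# peak starts uniformly within each chromosome, with the placement space
# scaled by a short-read mappability factor (0.88 for 25-bp tags).

#' Clustering parameters
#'
#' @param extension_length total extended peak length in bp (> 0).
#' @param min_cluster_size minimum number of member peaks for a region to
#'   count as a cluster (>= 2).
#' @param mappability fraction of each chromosome treated as mappable when
#'   shuffling, in (0, 1].
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(extension_length = 2000L, min_cluster_size = 2L,
                           mappability = 0.88) {
  if (extension_length <= 0) stop("extension_length must be > 0")
  if (min_cluster_size < 2) stop("min_cluster_size must be >= 2")
  if (mappability <= 0 || mappability > 1)
    stop("mappability must be in (0, 1]")
  structure(list(extension_length = as.integer(extension_length),
                 min_cluster_size = as.integer(min_cluster_size),
                 mappability = mappability),
            class = "cluster_config")
}

#' Extend peaks to a fixed total length
#'
#' Peaks shorter than `total_length` are replaced by an interval of that
#' length centred on the peak midpoint and clamped to chromosome bounds;
#' peaks already at least `total_length` long are returned unchanged.
#'
#' @param pk peak GRanges (see [peaks()]).
#' @param total_length target length in bp.
#' @param genome genome used for bounds; every peak chromosome must be
#'   present.
#' @return GRanges of extended intervals, parallel to `pk`.
#' @export
extend_peaks <- function(pk, total_length, genome) {
  if (total_length <= 0) stop("total_length must be > 0")
  unknown <- setdiff(as.character(unique(seqnames(pk))), names(genome))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  s0 <- start0(pk); e0 <- end0(pk)
  mid <- (s0 + e0) %/% 2L
  ns <- mid - total_length %/% 2L
  ne <- ns + as.integer(total_length)
  short <- width(pk) < total_length
  ns <- ifelse(short, ns, s0)
  ne <- ifelse(short, ne, e0)
  lens <- unname(genome[as.character(seqnames(pk))])
  ns <- pmax(ns, 0L)
  ne <- pmin(ne, lens)
  out <- GRanges(seqnames(pk), IRanges(ns + 1L, ne))
  mcols(out) <- mcols(pk)
  out
}

#' Build transcription factor clusters from peaks
#'
#' Extended peaks are merged; every merged region with at least
#' `min_cluster_size` member peaks is a cluster, the remaining regions
#' (singletons under the default size limit of 2) are returned separately.
#' The two sets partition the input peaks.
#'
#' @param pk peak GRanges (see [peaks()]).
#' @param config a [cluster_config()].
#' @param genome genome (named lengths).
#' @return object of class `cluster_set`: list with GRanges `clusters` and
#'   `singletons` (metadata columns `size`, `factors` comma-joined,
#'   `peak_ids` comma-joined, `members` index list into `peaks`), the input
#'   `peaks`, and `config`.
#' @export
build_clusters <- function(pk, config = cluster_config(), genome) {
  empty <- function() {
    g <- GRanges()
    mcols(g) <- DataFrame(size = integer(), factors = character(),
                          peak_ids = character())
    g
  }
  if (length(pk) == 0L)
    return(structure(list(clusters = empty(), singletons = empty(),
                          members = list(), singleton_members = list(),
                          peaks = pk, config = config),
                     class = "cluster_set"))
  ext <- extend_peaks(pk, config$extension_length, genome)
  red <- reduce(granges(ext), with.revmap = TRUE, ignore.strand = TRUE)
  members <- as.list(mcols(red)$revmap)
  sizes <- lengths(members)
  fac <- mcols(pk)$factor
  ids <- mcols(pk)$source_id
  annotate <- function(regions, mem) {
    mcols(regions) <- DataFrame(
      size = lengths(mem),
      factors = vapply(mem, function(i)
        paste(sort(unique(fac[i])), collapse = ","), ""),
      peak_ids = vapply(mem, function(i) paste(ids[i], collapse = ","), ""))
    regions
  }
  is_cl <- sizes >= config$min_cluster_size
  structure(list(
    clusters = annotate(granges(red)[is_cl], members[is_cl]),
    singletons = annotate(granges(red)[!is_cl], members[!is_cl]),
    members = members[is_cl],
    singleton_members = members[!is_cl],
    peaks = pk,
    config = config), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters,",
      length(x$singletons), "singletons,", length(x$peaks), "peaks\n")
  cat("  extension", x$config$extension_length, "bp; size limit",
      x$config$min_cluster_size, "\n")
  invisible(x)
}

# factor sets per cluster as a list of character vectors
cluster_factor_sets <- function(cs) {
  strsplit(mcols(cs$clusters)$factors, ",", fixed = TRUE)
}

#' Shuffle peak starts within chromosomes
#'
#' Every peak keeps its chromosome, length, factor and intensity; its
#' start is redrawn uniformly from `[0, mappability * L - length]` where
#' `L` is the chromosome length.  Used to build the random-cluster null.
#'
#' @param pk peak GRanges.
#' @param genome genome (named lengths).
#' @param mappability mappable fraction of each chromosome in (0, 1].
#' @param seed integer seed; fixing it fixes the output exactly.
#' @return shuffled peak GRanges.
#' @export
shuffle_peaks <- function(pk, genome, mappability = 0.88, seed = NULL) {
  if (mappability <= 0 || mappability > 1)
    stop("mappability must be in (0, 1]")
  unknown <- setdiff(as.character(unique(seqnames(pk))), names(genome))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  lens <- unname(genome[as.character(seqnames(pk))])
  space <- floor(mappability * lens) - width(pk)
  if (any(space < 0))
    stop("peak longer than the mappability-adjusted chromosome")
  ns <- as.integer(floor(runif(length(pk)) * (space + 1)))
  ns <- pmin(ns, as.integer(space))  # guard against runif() == 1 edge
  out <- GRanges(seqnames(pk), IRanges(ns + 1L, ns + width(pk)))
  mcols(out) <- mcols(pk)
  out
}

#' Cluster size histogram
#'
#' @param cs a `cluster_set` (or list with `clusters`/`singletons`).
#' @return named integer vector: number of regions per member-peak count,
#'   keyed from the smallest observed size upward.
#' @export
cluster_size_histogram <- function(cs) {
  sizes <- c(mcols(cs$clusters)$size, mcols(cs$singletons)$size)
  if (length(sizes) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(factor(sizes, levels = seq_len(max(sizes))))
  setNames(as.integer(tab), names(tab))
}

#' Mean region length by cluster size
#'
#' @param cs a `cluster_set`.
#' @return named numeric vector: mean merged-region length (bp) per size.
#' @export
mean_length_by_size <- function(cs) {
  sizes <- c(mcols(cs$clusters)$size, mcols(cs$singletons)$size)
  w <- c(width(cs$clusters), width(cs$singletons))
  if (length(sizes) == 0L) return(setNames(numeric(0), character(0)))
  out <- tapply(w, sizes, mean)
  setNames(as.numeric(out), names(out))
}

#' Quantile-bin peaks by ChIP tag intensity
#'
#' Peaks from one factor dataset are split into `n_bins` equal-count bins
#' of increasing intensity; bin `n_bins` holds the most intense peaks.
#' Bin sizes differ by at most one; ties are broken by stable input order.
#'
#' @param pk peak GRanges for a single factor dataset.
#' @param n_bins number of bins (>= 1).
#' @return named integer vector: bin index (1..n_bins) per `source_id`.
#' @export
bin_peaks_by_intensity <- function(pk, n_bins = 20L) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  n <- length(pk)
  if (n == 0L) return(setNames(integer(0), character(0)))
  ord <- order(mcols(pk)$intensity)        # stable for ties
  pos <- integer(n); pos[ord] <- seq_len(n)
  bin <- as.integer(ceiling(pos * n_bins / n))
  setNames(bin, mcols(pk)$source_id)
}
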