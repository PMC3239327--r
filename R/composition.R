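# Factor composition of cluster groups and coverage saturation curves.

#' Factor composition vector of a cluster group
#'
#' Entry f = fraction of clusters in the group containing at least one
#' peak of factor f.  The factor ordering is fixed by `factors` so vectors
#' from different groups are comparable.
#'
#' @param cs a `cluster_set`, or a list of character vectors (one factor
#'   set per cluster).
#' @param factors ordered character vector of factor names.
#' @param subset optional integer indices restricting the cluster group.
#' @return named numeric vector in [0, 1]; attribute `n_clusters` carries
#'   the group size and `empty = TRUE` flags a zero-vector from an empty
#'   group.
#' @export
composition_vector <- function(cs, factors, subset = NULL) {
  if (length(factors) == 0L) stop("factors must be nonempty")
  fsets <- if (inherits(cs, "cluster_set")) cluster_factor_sets(cs) else cs
  if (!is.null(subset)) fsets <- fsets[subset]
  n <- length(fsets)
  v <- if (n == 0L) setNames(numeric(length(factors)), factors)
       else vapply(factors, function(f)
         mean(vapply(fsets, function(s) f %in% s, TRUE)), numeric(1))
  structure(setNames(as.numeric(v), factors),
            n_clusters = n, empty = n == 0L)
}

#' Pearson correlation between two composition vectors
#'
#' Standard product-moment correlation over a shared factor ordering.
#' A constant vector has no defined correlation and is an error rather
#' than a silent zero.
#'
#' @param a,b numeric vectors of equal length >= 2 (same factor order).
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("vectors must have length >= 2")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop("factor orderings differ")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a constant vector")
  as.numeric(cor(a, b))
}

#' Coverage saturation curve over random factor orderings
#'
#' For a random ordering of the factors and each prefix of k factors, a
#' target region counts as covered when at least one qualifying peak of a
#' prefix factor overlaps it; qualifying peaks are the members of clusters
#' (default) or all peaks (`include_singletons = TRUE`, cluster membership
#' ignored).  The curve is the mean covered fraction per k over
#' `n_orders` shuffled orderings (or over all orderings when
#' `n_orders = NULL`).
#'
#' @param targets GRanges of target regions (e.g. promoters); must be
#'   nonempty.
#' @param cs a `cluster_set` supplying the peaks and cluster membership.
#' @param n_orders number of shuffled factor orders (default 100), or
#'   NULL for exhaustive enumeration of all permutations.
#' @param seed integer seed for the shuffled orders.
#' @param include_singletons use all peaks rather than cluster members.
#' @param factors factor ordering universe; defaults to the sorted factors
#'   present in the peaks.
#' @return object of class `coverage_curve`: numeric vector of length
#'   `n_factors + 1` (k = 0..n), with attributes `factors` and `n_orders`.
#' @export
coverage_curve <- function(targets, cs, n_orders = 100L, seed = NULL,
                           include_singletons = FALSE, factors = NULL) {
  if (length(targets) == 0L) stop("target set is empty")
  pk <- cs$peaks
  if (is.null(factors)) factors <- sort(unique(mcols(pk)$factor))
  nf <- length(factors)
  qualifying <- if (include_singletons) seq_along(pk)
                else sort(unique(unlist(cs$members, use.names = FALSE)))
  pk <- pk[qualifying]
  # cover[t, f]: target t touched by a qualifying peak of factor f
  cover <- matrix(FALSE, length(targets), nf, dimnames = list(NULL, factors))
  hits <- findOverlaps(targets, pk, ignore.strand = TRUE)
  if (length(hits)) {
    fi <- match(mcols(pk)$factor[subjectHits(hits)], factors)
    ok <- !is.na(fi)
    cover[cbind(queryHits(hits)[ok], fi[ok])] <- TRUE
  }
  curve_for <- function(ord) {
    cum <- matrixStats_rowCumAny(cover[, ord, drop = FALSE])
    c(0, colMeans(cum))
  }
  if (is.null(n_orders)) {
    orders <- permutations(nf)
    curves <- vapply(seq_len(nrow(orders)),
                     function(i) curve_for(orders[i, ]), numeric(nf + 1))
    n_used <- nrow(orders)
  } else {
    if (n_orders < 1) stop("n_orders must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    curves <- vapply(seq_len(n_orders),
                     function(i) curve_for(sample.int(nf)),
                     numeric(nf + 1))
    n_used <- n_orders
  }
  structure(rowMeans(curves), names = as.character(0:nf),
            factors = factors, n_orders = n_used, class = "coverage_curve")
}

#' @export
print.coverage_curve <- function(x, ...) {
  cat("coverage_curve over", length(attr(x, "factors")), "factors,",
      attr(x, "n_orders"), "orders\n")
  print(round(unclass(x), 4))
  invisible(x)
}

# cumulative "any" along columns, by row
matrixStats_rowCumAny <- function(m) {
  if (ncol(m) >= 2L)
    for (j in 2:ncol(m)) m[, j] <- m[, j] | m[, j - 1L]
  m
}

# all permutations of 1..n as rows (n small; used for exhaustive curves)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  if (n > 8L) stop("exhaustive enumeration limited to 8 factors")
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
    r <- r + nrow(sub)
  }
  out
}
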