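# Independent brute-force oracles and small fixture builders.  Oracles are
# deliberately naive (per-base masks, all-pairs scans, definitional
# formulas) and share no code with the implementation paths they check.

library(GenomicRanges)

# GRanges from 0-based half-open triples
gr0 <- function(chrom, s0, e0, ...) {
  GRanges(rep_len(chrom, length(s0)), IRanges(s0 + 1L, e0), ...)
}

# random unstranded intervals on a toy chromosome
random_intervals <- function(n, chrom_len = 10000L, max_len = 500L,
                             chrom = "chr1") {
  s0 <- floor(runif(n) * (chrom_len - max_len))
  w <- 1L + floor(runif(n) * max_len)
  gr0(chrom, s0, s0 + w)
}

# oracle: union of covered bases via a per-base boolean mask
mask_union <- function(gr, chrom_len = 10000L) {
  out <- list()
  for (ch in unique(as.character(seqnames(gr)))) {
    mask <- logical(chrom_len)
    sub <- gr[seqnames(gr) == ch]
    for (i in seq_along(sub))
      mask[(start(sub)[i]):(end(sub)[i])] <- TRUE   # 1-based positions
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      out[[ch]] <- GRanges(ch, IRanges(starts[keep], ends[keep]))
  }
  if (length(out) == 0L) return(GRanges())
  sort(do.call(c, unname(out)))
}

# oracle: all-pairs >= 1 bp overlap scan on plain vectors
bf_overlap_fraction <- function(query, subject) {
  if (length(query) == 0L) return(0)
  qc <- as.character(seqnames(query)); qs <- start(query); qe <- end(query)
  sc <- as.character(seqnames(subject)); ss <- start(subject); se <- end(subject)
  hit <- vapply(seq_along(query), function(i)
    any(qc[i] == sc & qs[i] <= se & ss <= qe[i]), TRUE)
  mean(hit)
}

# oracle: connected components of the extended-interval overlap graph,
# via an O(n^2) adjacency matrix and igraph
bf_components <- function(ext) {
  n <- length(ext)
  if (n == 0L) return(integer(0))
  chrom <- as.character(seqnames(ext))
  s <- start(ext); e <- end(ext)
  adj <- outer(chrom, chrom, "==") &
    outer(s, e, "<=") & t(outer(s, e, "<="))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

# canonical form of a partition-into-components for comparison
partition_key <- function(membership) {
  unname(lapply(
    split(seq_along(membership), membership)[
      order(vapply(split(seq_along(membership), membership), min, 0L))],
    identity))
}

# oracle: definitional two-pass Pearson correlation
bf_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# oracle: exact coverage curve by exhaustive enumeration of factor orders,
# from a logical target x factor coverage matrix
bf_coverage_exhaustive <- function(cover) {
  nf <- ncol(cover)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  all_orders <- perms(seq_len(nf))
  acc <- numeric(nf + 1)
  for (ord in all_orders) {
    seen <- rep(FALSE, nrow(cover))
    for (k in seq_len(nf)) {
      seen <- seen | cover[, ord[k]]
      acc[k + 1] <- acc[k + 1] + mean(seen)
    }
  }
  acc / length(all_orders)
}

# small multi-factor peak set builder
make_peaks <- function(chrom, s0, e0, factor, intensity = 1) {
  peaks(gr0(chrom, s0, e0), factor = factor, intensity = intensity)
}

toy_genome <- genome(c(chr1 = 1e6, chr2 = 1e6))
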