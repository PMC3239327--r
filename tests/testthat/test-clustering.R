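# Peak extension, cluster construction and the shuffle null.

test_that("extend_peaks centres on the midpoint and clamps", {
  gnm <- toy_genome
  pk <- make_peaks("chr1", 5000, 5100, "A")
  ext <- extend_peaks(pk, 2000, gnm)
  expect_equal(c(start0(ext), end0(ext)), c(4050, 6050))

  near <- make_peaks("chr1", 0, 100, "A")
  ext <- extend_peaks(near, 2000, gnm)
  expect_equal(c(start0(ext), end0(ext)), c(0, 1050))

  long <- make_peaks("chr1", 10000, 13000, "A")
  expect_equal(width(extend_peaks(long, 2000, gnm)), 3000)
  expect_error(extend_peaks(make_peaks("chrX", 0, 10, "A"), 2000, gnm),
               "unknown chromosome")
})

test_that("build_clusters groups peaks by extended overlap", {
  gnm <- toy_genome
  pk <- make_peaks("chr1", c(5000, 6000), c(5100, 6100), c("A", "B"))
  cs <- build_clusters(pk, cluster_config(), gnm)
  expect_length(cs$clusters, 1)
  expect_length(cs$singletons, 0)
  expect_equal(mcols(cs$clusters)$size, 2)
  expect_equal(c(start0(cs$clusters), end0(cs$clusters)), c(4050, 7050))
  expect_equal(mcols(cs$clusters)$factors, "A,B")

  pk3 <- make_peaks("chr1", c(5000, 6000, 9000), c(5100, 6100, 9100),
                    c("A", "B", "A"))
  cs3 <- build_clusters(pk3, cluster_config(), gnm)
  expect_length(cs3$clusters, 1)
  expect_length(cs3$singletons, 1)
  expect_equal(c(start0(cs3$singletons), end0(cs3$singletons)),
               c(8050, 10050))

  cs0 <- build_clusters(make_peaks("chr1", integer(0), integer(0),
                                   character(0)), cluster_config(), gnm)
  expect_length(cs0$clusters, 0)
  expect_length(cs0$singletons, 0)
})

test_that("cluster membership partitions the peaks on random inputs", {
  set.seed(3)
  gnm <- toy_genome
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    pk <- peaks(random_intervals(n, chrom_len = 5e5,
                                 chrom = sample(c("chr1", "chr2"), 1)),
                factor = sample(LETTERS[1:5], n, replace = TRUE))
    cs <- build_clusters(pk, cluster_config(), gnm)
    idx <- c(unlist(cs$members), unlist(cs$singleton_members))
    expect_equal(sort(idx), seq_len(n))   # exactly one home per peak
    expect_equal(sum(mcols(cs$clusters)$size) +
                   sum(mcols(cs$singletons)$size), n)
  }
})

test_that("raising min_cluster_size only removes clusters", {
  set.seed(8)
  pk <- peaks(random_intervals(150, chrom_len = 4e5), factor = "A")
  cs2 <- build_clusters(pk, cluster_config(min_cluster_size = 2), toy_genome)
  cs3 <- build_clusters(pk, cluster_config(min_cluster_size = 3), toy_genome)
  expect_lte(length(cs3$clusters), length(cs2$clusters))
  k2 <- paste(seqnames(cs2$clusters), start(cs2$clusters))
  k3 <- paste(seqnames(cs3$clusters), start(cs3$clusters))
  expect_true(all(k3 %in% k2))
})

test_that("shuffle_peaks conserves the per-chromosome length multiset", {
  set.seed(5)
  n <- 80
  pk <- peaks(random_intervals(n, chrom_len = 9e5), factor = "A",
              intensity = runif(n))
  sh <- shuffle_peaks(pk, toy_genome, 0.88, seed = 10)
  key <- function(g) sort(paste(seqnames(g), width(g), mcols(g)$factor))
  expect_equal(key(sh), key(pk))
  expect_equal(sort(mcols(sh)$intensity), sort(mcols(pk)$intensity))

  expect_identical(shuffle_peaks(pk, toy_genome, 0.88, seed = 10), sh)
  sh2 <- shuffle_peaks(pk, toy_genome, 0.88, seed = 11)
  expect_false(identical(start(sh2), start(sh)))
})

test_that("shuffle placement respects the mappability-scaled space", {
  pk <- peaks(gr0("chr1", rep(0, 500), rep(100, 500)), factor = "A")
  sh <- shuffle_peaks(pk, genome(c(chr1 = 1e6)), 0.88, seed = 1)
  expect_true(all(start0(sh) >= 0))
  expect_true(all(start0(sh) <= 879900))  # 0.88e6 - 100
  expect_gt(max(start0(sh)), 700000)      # space actually used
  big <- peaks(gr0("chr1", 0, 950000), factor = "A")
  expect_error(shuffle_peaks(big, genome(c(chr1 = 1e6)), 0.88, seed = 1),
               "longer than")
})

test_that("size histogram and mean lengths summarise regions", {
  gnm <- toy_genome
  pk <- make_peaks("chr1",
                   c(5000, 6000, 20000, 21000, 40000, 41000, 60000,
                     100000, 200000, 300000),
                   c(5100, 6100, 20100, 21100, 40100, 41100, 60100,
                     100100, 200100, 300100),
                   rep(c("A", "B"), 5))
  cs <- build_clusters(pk, cluster_config(), gnm)
  h <- cluster_size_histogram(cs)
  expect_equal(unname(h[c("1", "2")]), c(4, 3))
  expect_equal(sum(as.integer(names(h)) * h), length(pk))
  # singletons of short peaks sit at the extension floor
  ml <- mean_length_by_size(cs)
  expect_equal(unname(ml["1"]), 2000)
  expect_equal(unname(ml["2"]), 3000)     # extension 2000 + midpoint span
  empty <- build_clusters(make_peaks("chr1", integer(0), integer(0),
                                     character(0)), cluster_config(), gnm)
  expect_length(cluster_size_histogram(empty), 0)
})

test_that("intensity binning is equal-count with stable ties", {
  pk <- peaks(random_intervals(40), factor = "A", intensity = sample(40))
  b <- bin_peaks_by_intensity(pk, 20)
  expect_equal(as.integer(table(b)), rep(2L, 20))
  top2 <- mcols(pk)$source_id[order(-mcols(pk)$intensity)][1:2]
  expect_equal(unname(b[top2]), c(20L, 20L))
  # oracle: sort + slice
  ord <- order(mcols(pk)$intensity)
  expected <- integer(40); expected[ord] <- rep(1:20, each = 2)
  expect_equal(unname(b), expected)

  one_per <- bin_peaks_by_intensity(peaks(random_intervals(20), "A",
                                          intensity = 20:1), 20)
  expect_equal(sort(unname(one_per)), 1:20)

  tied <- peaks(random_intervals(11), "A", intensity = rep(5, 11))
  bt <- bin_peaks_by_intensity(tied, 3)
  expect_lte(diff(range(table(bt))), 1)
  expect_true(!is.unsorted(unname(bt)))   # stable input order fills bins
})
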