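# Transcript/enhancer classification and mark overlap summaries.

# one cluster per 100-kb slot on chr1, factors A+B
slot_clusters <- function(n_slots) {
  s0 <- seq(100000, by = 100000, length.out = n_slots)
  pk <- make_peaks("chr1", rep(s0, each = 2) + c(0, 500),
                   rep(s0, each = 2) + c(200, 700),
                   rep(c("A", "B"), n_slots))
  build_clusters(pk, cluster_config(), toy_genome)
}

empty_marks <- function(...) {
  base <- list(H3K36me3 = GRanges(), H3K4me3 = GRanges(), PolII = GRanges())
  mark_library(utils::modifyList(base, list(...)))
}

test_that("transcript calls need H3K36me3, Pol II/III or linked H3K4me3", {
  cs <- slot_clusters(5)
  s0 <- start0(cs$clusters)
  ml <- empty_marks(
    H3K36me3 = gr0("chr1", s0[1] - 100, s0[1] + 100),
    PolII = gr0("chr1", c(s0[2] - 100, 400000 - 60000),
                c(s0[2] + 100, 400000 - 59000)),
    # cluster 3: isolated H3K4me3; cluster 4: H3K4me3 linked to a PolII
    # domain that the cluster itself does not touch
    H3K4me3 = gr0("chr1", c(s0[3] - 100, s0[4] - 60200),
                  c(s0[3] + 100, s0[4] + 300)),
    PolIII = gr0("chr1", s0[5] - 100, s0[5] + 100))
  # the H3K4me3 domain of cluster 4 stretches back to touch the PolII
  # domain at 340000..341000 => linked
  cls <- classify_clusters(cs, ml, exclude_factors = character(0))
  expect_equal(cls$class,
               c("transcript", "transcript", "enhancer", "transcript",
                 "transcript"))
  expect_equal(cls$provenance,
               c("H3K36me3", "PolII", "none", "H3K4me3-linked", "PolIII"))
})

test_that("clusters made only of excluded factors are dropped", {
  s0 <- c(100000, 200000, 300000)
  pk <- make_peaks("chr1", rep(s0, each = 2) + c(0, 500),
                   rep(s0, each = 2) + c(200, 700),
                   c("CTCF", "Rad21", "CTCF", "A", "A", "B"))
  cs <- build_clusters(pk, cluster_config(), toy_genome)
  cls <- classify_clusters(cs, empty_marks())
  expect_equal(cls$cluster, 2:3)           # mixed cluster 2 is kept
  expect_true(all(cls$class == "enhancer"))
  expect_error(classify_clusters(cs, mark_library(list(H3K4me3 = GRanges()))),
               "H3K36me3")
})

test_that("adding mark regions never turns transcript into enhancer", {
  set.seed(21)
  cs <- slot_clusters(8)
  s0 <- start0(cs$clusters)
  base <- empty_marks(H3K36me3 = gr0("chr1", s0[c(1, 3)], s0[c(1, 3)] + 50))
  more <- empty_marks(
    H3K36me3 = gr0("chr1", s0[c(1, 3, 5)], s0[c(1, 3, 5)] + 50),
    PolII = gr0("chr1", s0[7], s0[7] + 50))
  c1 <- classify_clusters(cs, base, exclude_factors = character(0))
  c2 <- classify_clusters(cs, more, exclude_factors = character(0))
  was_tx <- c1$cluster[c1$class == "transcript"]
  expect_true(all(c2$class[c2$cluster %in% was_tx] == "transcript"))
})

test_that("cross_tabulate conserves cluster counts", {
  cs <- slot_clusters(4)
  cls <- data.frame(cluster = 1:4,
                    class = c("transcript", "transcript", "enhancer",
                              "enhancer"),
                    provenance = c("H3K36me3", "PolII", "none", "none"))
  ctx <- data.frame(context = c("promoter", "gene", "intergenic", "gene"),
                    gene_id = c("g1", "g2", NA, "g3"))
  ec <- c(g1 = "high", g2 = "zero", g3 = "medium_low")
  xt <- cross_tabulate(cls, ctx, ec)
  expect_equal(sum(xt$by_annotation), 4)
  expect_equal(as.integer(xt$by_annotation["transcript", ]), c(2, 0))
  expect_equal(as.integer(xt$by_annotation["enhancer", ]), c(1, 1))
  expect_equal(sum(xt$by_expression), 3)   # intergenic cluster has no gene
  expect_equal(as.integer(xt$by_expression["transcript",
                                           c("high", "zero")]), c(1, 1))

  none <- cross_tabulate(cls[0, ], ctx[0, ], ec)
  expect_equal(sum(none$by_annotation), 0)
})

test_that("enhancer marker fractions recover emission probabilities", {
  cs <- slot_clusters(6)
  ml <- empty_marks(H3K4me1 = granges(cs$clusters),
                    H3K27ac = GRanges())
  ov <- enhancer_marker_overlap(cs$clusters, ml,
                                c("H3K4me1", "H3K27ac"))
  expect_equal(unname(ov), c(1, 0))
  expect_error(enhancer_marker_overlap(cs$clusters, ml, "p300"),
               "no such mark")

  # binomial recovery at n = 1000 planted intergenic enhancers
  cfg <- synthetic_config(
    genome = c(chr1 = 30e6, chr2 = 30e6), n_genes = 60,
    element_counts = c(intergenic_enhancer = 1000),
    noise_rate_per_mb = 0, seed = 97)
  sim <- generate_synthetic(cfg)
  cs2 <- build_clusters(sim$peaks, cluster_config(), sim$genome)
  ml2 <- mark_library(sim$marks)
  ov2 <- enhancer_marker_overlap(cs2$clusters, ml2,
                                 c("H3K4me1", "H3K27ac"))
  expect_lt(abs(ov2[["H3K4me1"]] - 0.90), 0.05)
  expect_lt(abs(ov2[["H3K27ac"]] - 0.40), 0.05)
})

test_that("redundancy_ratio counts occupied mark regions", {
  cs <- slot_clusters(2)
  mark6 <- gr0("chr1", seq(1e5, by = 1e5, length.out = 6) - 50,
               seq(1e5, by = 1e5, length.out = 6) + 50)
  expect_equal(redundancy_ratio(mark6, cs$clusters), 3)   # 6 regions, 2 hit
  expect_equal(redundancy_ratio(mark6[1:2], cs$clusters), 1)
  far <- gr0("chr2", c(0, 1000), c(100, 1100))
  expect_equal(suppressWarnings(redundancy_ratio(far, cs$clusters)), 0)

  # invariant under splitting clusters while preserving occupancy
  split_regions <- split_to_max_length(cs$clusters, 200)
  expect_equal(redundancy_ratio(mark6, split_regions),
               redundancy_ratio(mark6, cs$clusters))
})
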