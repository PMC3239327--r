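# Nonredundant gene selection, expression classes, promoters and cluster
# gene context.

two_exon_gene <- function(id, chrom, strand, s0, e0, expr,
                          exons = NULL) {
  if (is.null(exons)) exons <- list(c(s0, s0 + 200), c(e0 - 200, e0))
  gene_table(id, chrom, strand, s0, e0,
             exon_starts = list(vapply(exons, `[`, 0, 1)),
             exon_ends = list(vapply(exons, `[`, 0, 2)),
             expression = expr)
}

test_that("select_nonredundant keeps the top-expressed gene per group", {
  g <- rbind(two_exon_gene("a", "chr1", "+", 1000, 5000, 5),
             two_exon_gene("b", "chr1", "+", 1100, 5100, 3))  # shares exons
  expect_equal(select_nonredundant(g)$id, "a")

  opp <- rbind(two_exon_gene("a", "chr1", "+", 1000, 5000, 5),
               two_exon_gene("b", "chr1", "-", 1000, 5000, 3))
  expect_equal(select_nonredundant(opp)$id, c("a", "b"))

  single <- two_exon_gene("solo", "chr1", "+", 1000, 5000, 1)
  expect_equal(select_nonredundant(single)$id, "solo")

  # transitive grouping: a~b and b~c collapse to one winner even when
  # a and c share no exon
  chain <- rbind(
    gene_table("a", "chr1", "+", 1000, 2000, list(1000), list(1500), expression = 1),
    gene_table("b", "chr1", "+", 1400, 3000, list(1400), list(2600), expression = 2),
    gene_table("c", "chr1", "+", 2500, 4000, list(2500), list(3000), expression = 9))
  expect_equal(select_nonredundant(chain)$id, "c")
  # no same-strand exon overlap remains
  out <- select_nonredundant(chain)
  expect_equal(nrow(out), 1)
})

test_that("expression classes follow the floor(n/3) tertile rule", {
  e <- c(10, 9, 8, 7, 6, 5, 4, 3, 0)
  g <- gene_table(letters[1:9], "chr1", "+",
                  seq(0, by = 10000, length.out = 9),
                  seq(5000, by = 10000, length.out = 9),
                  expression = e)
  cls <- classify_expression(g)
  expect_equal(unname(cls[c("a", "b", "c")]), rep("high", 3))
  expect_equal(unname(cls["i"]), "zero")
  expect_equal(unname(cls[letters[4:8]]), rep("medium_low", 5))
  expect_setequal(names(cls), g$id)         # classes partition the genes

  allz <- gene_table(c("x", "y", "z"), "chr1", "+", c(0, 1e4, 2e4),
                     c(5e3, 1.5e4, 2.5e4), expression = 0)
  expect_true(all(classify_expression(allz) == "zero"))

  two <- gene_table(c("x", "y"), "chr1", "+", c(0, 1e4), c(5e3, 1.5e4),
                    expression = c(4, 2))
  expect_false(any(classify_expression(two) == "high"))  # floor(2/3) = 0
})

test_that("promoter intervals are strand-oriented mirrors about the TSS", {
  plus <- gene_table("p", "chr1", "+", 10000, 30000)
  minus <- gene_table("m", "chr1", "-", 2000, 10000)  # TSS also at 10,000
  pp <- promoter_intervals(plus)
  pm <- promoter_intervals(minus)
  expect_equal(c(start0(pp), end0(pp)), c(8000, 10200))
  expect_equal(c(start0(pm), end0(pm)), c(9800, 12000))
  # mirror images about the shared TSS
  expect_equal(10000 - start0(pp), end0(pm) - 10000)
  expect_equal(end0(pp) - 10000, 10000 - start0(pm))

  near <- gene_table("n", "chr1", "+", 1000, 8000)
  pn <- promoter_intervals(near, genome = toy_genome)
  expect_equal(c(start0(pn), end0(pn)), c(0, 1200))
})

test_that("gene context prefers promoter, then gene window, else intergenic", {
  g <- gene_table("g1", "chr1", "+", 100000, 150000, expression = 5)
  ctx_of <- function(s0, e0)
    assign_gene_context(gr0("chr1", s0, e0), g)$context
  expect_equal(ctx_of(99400, 99600), "promoter")      # 500 bp upstream
  expect_equal(ctx_of(94900, 95100), "gene")          # 5 kb upstream
  expect_equal(ctx_of(120000, 121000), "gene")        # gene body
  expect_equal(ctx_of(200000, 201000), "intergenic")  # 50 kb away
  expect_equal(assign_gene_context(gr0("chr1", 99400, 99600), g)$gene_id,
               "g1")

  # nearest TSS wins among multiple qualifying genes
  g2 <- rbind(g, gene_table("g2", "chr1", "+", 140000, 190000,
                            expression = 1))
  hit <- assign_gene_context(gr0("chr1", 139000, 139500), g2)
  expect_equal(hit$context, "promoter")
  expect_equal(hit$gene_id, "g2")
})

test_that("tss_profile bins midpoints by signed strand-oriented distance", {
  gp <- gene_table("p", "chr1", "+", 50000, 80000)
  prof <- tss_profile(gr0("chr1", 50100, 50200), gp, window = 2000)
  expect_equal(sum(prof), 1)
  expect_equal(unname(prof["[0,200)"]), 1)   # midpoint at TSS + 150

  # minus strand: a midpoint 150 bp left of the TSS is downstream (+150),
  # one 150 bp right of it is upstream (-150)
  gm <- gene_table("m", "chr1", "-", 20000, 50150)
  prof_m <- tss_profile(gr0("chr1", 50250, 50350), gm, window = 2000)
  expect_equal(unname(prof_m["[-200,0)"]), 1)
  prof_m2 <- tss_profile(gr0("chr1", 49950, 50050), gm, window = 2000)
  expect_equal(unname(prof_m2["[0,200)"]), 1)

  expect_equal(sum(tss_profile(GRanges(), gp, window = 2000)), 0)
  expect_error(tss_profile(GRanges(), gp, window = 1000, bin = 300),
               "multiple")
})
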