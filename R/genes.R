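# Gene annotation: nonredundant gene selection, expression classes,
# promoters and the promoter/gene/intergenic context of clusters.
#
# Genes are a plain data.frame (refGene-like) with 0-based half-open
# transcript and exon coordinates and a per-gene expression value (mean
# RNA-Seq tag intensity over exons).  The TSS is tx_start on "+" and
# tx_end on "-".

#' Construct a gene table
#'
#' @param id gene identifiers (unique).
#' @param chrom chromosome per gene.
#' @param strand "+" or "-".
#' @param tx_start,tx_end transcript span, 0-based half-open.
#' @param exon_starts,exon_ends list of integer vectors (0-based half-open,
#'   sorted, within the transcript span).
#' @param expression nonnegative mean exon tag intensity (default 0).
#' @return data.frame with list-columns `exon_starts`, `exon_ends`.
#' @export
gene_table <- function(id, chrom, strand, tx_start, tx_end,
                       exon_starts = NULL, exon_ends = NULL,
                       expression = 0) {
  n <- length(id)
  if (anyDuplicated(id)) stop("gene ids must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(tx_start < 0) || any(tx_start >= tx_end))
    stop("transcript spans must satisfy 0 <= tx_start < tx_end")
  if (is.null(exon_starts)) {
    exon_starts <- as.list(tx_start)
    exon_ends <- as.list(tx_end)
  }
  expression <- rep_len(as.numeric(expression), n)
  if (any(expression < 0)) stop("expression must be >= 0")
  out <- data.frame(id = as.character(id), chrom = as.character(chrom),
                    strand = strand,
                    tx_start = as.integer(tx_start),
                    tx_end = as.integer(tx_end),
                    expression = expression,
                    stringsAsFactors = FALSE)
  out$exon_starts <- lapply(exon_starts, as.integer)
  out$exon_ends <- lapply(exon_ends, as.integer)
  for (i in seq_len(n)) {
    es <- out$exon_starts[[i]]; ee <- out$exon_ends[[i]]
    if (length(es) != length(ee) || any(es >= ee) || is.unsorted(es) ||
        es[1] < out$tx_start[i] || ee[length(ee)] > out$tx_end[i])
      stop("invalid exon structure for gene ", out$id[i])
  }
  out
}

#' TSS positions (0-based) of a gene table
#' @param genes a [gene_table()].
#' @return integer vector: tx_start on "+", tx_end on "-".
#' @export
tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
}

#' Read a refGene-like gene table
#'
#' Tab-separated with header: id, chrom, strand, txStart, txEnd, exonCount,
#' exonStarts, exonEnds (comma-separated lists) and optionally expression.
#'
#' @param path gene table path.
#' @param expression_path optional two-column (id, expression) table merged
#'   onto the genes; genes absent from it get expression 0.
#' @return a [gene_table()].
#' @export
read_genes <- function(path, expression_path = NULL) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  split_pos <- function(x) lapply(strsplit(as.character(x), ","),
                                  function(v) as.integer(v[nzchar(v)]))
  expr <- if ("expression" %in% names(tab)) tab$expression else 0
  if (!is.null(expression_path)) {
    et <- read_expression(expression_path)
    expr <- unname(et[tab$id])
    expr[is.na(expr)] <- 0
  }
  gene_table(tab$id, tab$chrom, tab$strand, tab$txStart, tab$txEnd,
             split_pos(tab$exonStarts), split_pos(tab$exonEnds), expr)
}

#' Write a gene table in refGene-like form
#' @param genes a [gene_table()].
#' @param path output path.
#' @param with_expression include the expression column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, with_expression = TRUE) {
  join <- function(col) vapply(col, function(v) paste0(paste(v, collapse = ","), ","), "")
  d <- data.frame(id = genes$id, chrom = genes$chrom, strand = genes$strand,
                  txStart = genes$tx_start, txEnd = genes$tx_end,
                  exonCount = lengths(genes$exon_starts),
                  exonStarts = join(genes$exon_starts),
                  exonEnds = join(genes$exon_ends))
  if (with_expression) d$expression <- genes$expression
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column expression table
#' @param path tab-separated (id, mean exon tag intensity), with header.
#' @return named numeric vector keyed by gene id.
#' @export
read_expression <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Write an expression table
#' @param genes a [gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(genes, path) {
  write.table(data.frame(id = genes$id, expression = genes$expression),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

exon_granges <- function(genes) {
  k <- lengths(genes$exon_starts)
  idx <- rep(seq_len(nrow(genes)), k)
  GRanges(genes$chrom[idx],
          IRanges(unlist(genes$exon_starts) + 1L, unlist(genes$exon_ends)),
          strand = genes$strand[idx], gene = idx)
}

#' Select nonredundant genes
#'
#' Genes whose exons overlap on the same strand are grouped transitively;
#' from each group only the gene with the highest expression is kept (ties:
#' longest transcript, then lexicographic id).
#'
#' @param genes a [gene_table()].
#' @return the nonredundant subset, original order preserved.
#' @export
select_nonredundant <- function(genes) {
  n <- nrow(genes)
  if (n <= 1L) return(genes)
  ex <- exon_granges(genes)
  hits <- findOverlaps(ex, ex)            # strand-aware by default
  gi <- mcols(ex)$gene[queryHits(hits)]
  gj <- mcols(ex)$gene[subjectHits(hits)]
  edges <- unique(cbind(pmin(gi, gj), pmax(gi, gj))[gi != gj, , drop = FALSE])
  g <- igraph::make_graph(as.vector(t(edges)), n = n, directed = FALSE)
  group <- igraph::components(g)$membership
  len <- genes$tx_end - genes$tx_start
  ord <- order(group, -genes$expression, -len, genes$id)
  pick <- ord[!duplicated(group[ord])]
  genes[sort(pick), , drop = FALSE]
}

#' Classify genes by expression
#'
#' The floor(n/3) highest-expression genes are "high" (transcribed); genes
#' with zero expression are "zero" (silent); the rest are "medium_low".  A
#' zero-expression gene is never "high", so when fewer than floor(n/3)
#' genes are expressed the high class is smaller (empty if all are zero).
#' Ties at the boundary resolve by descending expression then id.
#'
#' @param genes a [gene_table()].
#' @return named character vector (gene id -> class).
#' @export
classify_expression <- function(genes) {
  n <- nrow(genes)
  cls <- rep("medium_low", n)
  cls[genes$expression == 0] <- "zero"
  k <- n %/% 3L
  if (k > 0L) {
    ord <- order(-genes$expression, genes$id)
    top <- ord[seq_len(k)]
    cls[top[genes$expression[top] > 0]] <- "high"
  }
  setNames(cls, genes$id)
}

#' Promoter intervals
#'
#' The promoter is the window from `upstream` bp upstream to `downstream`
#' bp downstream of the TSS, strand-oriented and clamped to chromosome
#' bounds: `[TSS - 2000, TSS + 200)` on "+" by default.
#'
#' @param genes a [gene_table()].
#' @param upstream,downstream window extents in bp.
#' @param genome optional genome for clamping.
#' @return GRanges with metadata column `gene_id`.
#' @export
promoter_intervals <- function(genes, upstream = 2000L, downstream = 200L,
                               genome = NULL) {
  t0 <- tss(genes)
  plus <- genes$strand == "+"
  s0 <- ifelse(plus, t0 - upstream, t0 - downstream)
  e0 <- ifelse(plus, t0 + downstream, t0 + upstream)
  s0 <- pmax(s0, 0L)
  if (!is.null(genome)) e0 <- pmin(e0, unname(genome[genes$chrom]))
  GRanges(genes$chrom, IRanges(s0 + 1L, e0), strand = genes$strand,
          gene_id = genes$id)
}

# gene window = gene body plus `upstream_limit` bp upstream of the TSS
gene_windows <- function(genes, upstream_limit = 10000L, genome = NULL) {
  plus <- genes$strand == "+"
  s0 <- ifelse(plus, genes$tx_start - upstream_limit, genes$tx_start)
  e0 <- ifelse(plus, genes$tx_end, genes$tx_end + upstream_limit)
  s0 <- pmax(s0, 0L)
  if (!is.null(genome)) e0 <- pmin(e0, unname(genome[genes$chrom]))
  GRanges(genes$chrom, IRanges(s0 + 1L, e0), gene_id = genes$id)
}

#' Assign gene context to cluster regions
#'
#' A region overlapping any promoter is a "promoter" cluster; otherwise a
#' region overlapping a gene body or the window up to
#' `upstream_gene_limit` bp upstream of a TSS is a "gene" cluster;
#' everything else is "intergenic".  When several genes qualify, the gene
#' whose TSS is nearest to the region midpoint is assigned.
#'
#' @param regions GRanges of cluster regions.
#' @param genes nonredundant [gene_table()].
#' @param upstream,downstream promoter window (bp).
#' @param upstream_gene_limit upstream extent of the gene window (bp).
#' @param genome optional genome for clamping.
#' @return data.frame with columns `context` ("promoter"/"gene"/
#'   "intergenic") and `gene_id` (NA for intergenic), one row per region.
#' @export
assign_gene_context <- function(regions, genes, upstream = 2000L,
                                downstream = 200L,
                                upstream_gene_limit = 10000L,
                                genome = NULL) {
  n <- length(regions)
  context <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L || nrow(genes) == 0L)
    return(data.frame(context = context, gene_id = gene_id))
  t0 <- tss(genes)
  mid <- (start0(regions) + end0(regions)) %/% 2L
  assign_nearest <- function(hits, which_rows) {
    # among qualifying genes, pick the nearest TSS per region
    d <- abs(mid[queryHits(hits)] - t0[subjectHits(hits)])
    ord <- order(queryHits(hits), d)
    first <- ord[!duplicated(queryHits(hits)[ord])]
    setNames(genes$id[subjectHits(hits)[first]],
             queryHits(hits)[first])
  }
  prom <- promoter_intervals(genes, upstream, downstream, genome)
  ph <- findOverlaps(regions, prom, ignore.strand = TRUE)
  if (length(ph)) {
    got <- assign_nearest(ph)
    idx <- as.integer(names(got))
    context[idx] <- "promoter"
    gene_id[idx] <- unname(got)
  }
  rest <- which(context == "intergenic")
  if (length(rest)) {
    gw <- gene_windows(genes, upstream_gene_limit, genome)
    gh <- findOverlaps(regions[rest], gw, ignore.strand = TRUE)
    if (length(gh)) {
      d <- abs(mid[rest][queryHits(gh)] - t0[subjectHits(gh)])
      ord <- order(queryHits(gh), d)
      first <- ord[!duplicated(queryHits(gh)[ord])]
      idx <- rest[queryHits(gh)[first]]
      context[idx] <- "gene"
      gene_id[idx] <- genes$id[subjectHits(gh)[first]]
    }
  }
  data.frame(context = context, gene_id = gene_id)
}

#' TSS-centred profile of region midpoints
#'
#' Counts region midpoints in fixed-width bins of signed, strand-oriented
#' distance from the nearest TSS (negative = upstream).  Midpoints farther
#' than `window` from every TSS are not counted.
#'
#' @param regions GRanges.
#' @param genes a [gene_table()] supplying the TSSs.
#' @param window half-width of the profile in bp (multiple of `bin`).
#' @param bin bin width in bp.
#' @return named integer vector of counts, one per bin over
#'   `[-window, window)`, names like `"[-2000,-1800)"`.
#' @export
tss_profile <- function(regions, genes, window, bin = 200L) {
  if (window %% bin != 0) stop("window must be a multiple of bin")
  nb <- 2L * window %/% bin
  lo <- seq(-window, window - bin, by = bin)
  labels <- sprintf("[%d,%d)", lo, lo + bin)
  counts <- setNames(integer(nb), labels)
  if (length(regions) == 0L || nrow(genes) == 0L) return(counts)
  mid <- (start0(regions) + end0(regions)) %/% 2L
  t0 <- tss(genes)
  sgn <- ifelse(genes$strand == "+", 1L, -1L)
  chrom <- as.character(seqnames(regions))
  for (i in seq_along(regions)) {
    same <- which(genes$chrom == chrom[i])
    if (!length(same)) next
    j <- same[which.min(abs(mid[i] - t0[same]))]
    dd <- (mid[i] - t0[j]) * sgn[j]
    if (dd >= -window && dd < window) {
      b <- (dd + window) %/% bin + 1L
      counts[b] <- counts[b] + 1L
    }
  }
  counts
}
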