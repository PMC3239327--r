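# Synthetic genome with planted regulatory elements and a ground-truth
# manifest.
#
# The generator emulates the statistical structure the pipeline is built
# to recover: genes with zero-inflated log-normal expression; promoter
# elements planted at TSSs of transcribed (active) and silent genes;
# enhancer elements inside gene bodies and far from genes; intergenic
# transcript units; per-class factor-composition probabilities driving
# multi-factor peak emission; per-class chromatin-domain emission
# (H3K4me1/2/3, H3K27ac, H3K9ac, H3K36me3, H3K27me3, Pol II/III, OCR)
# with optional dropout; and uniform noise peaks.  Elements are spaced so
# that, at zero noise and zero dropout, every planted label is exactly
# recoverable by the downstream rules.

synthetic_classes <- c("active_promoter", "silent_promoter",
                       "genic_enhancer", "intergenic_enhancer",
                       "intergenic_transcript_unit")

synthetic_marks <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K27ac", "H3K9ac",
                     "H3K36me3", "H3K27me3", "PolII", "PolIII", "OCR")

default_factors <- c("CTCF", "Rad21", paste0("TF", sprintf("%02d", 1:10)))

default_composition <- function(factors = default_factors) {
  m <- rbind(
    active_promoter            = c(0.20, 0.20, 0.85, 0.85, 0.80, 0.80, 0.75, 0.30, 0.30, 0.10, 0.05, 0.05),
    silent_promoter            = c(0.60, 0.60, 0.10, 0.10, 0.50, 0.10, 0.10, 0.20, 0.20, 0.60, 0.50, 0.40),
    genic_enhancer             = c(0.50, 0.50, 0.10, 0.10, 0.20, 0.30, 0.70, 0.70, 0.60, 0.60, 0.30, 0.20),
    intergenic_enhancer        = c(0.40, 0.40, 0.05, 0.05, 0.10, 0.20, 0.30, 0.70, 0.70, 0.70, 0.60, 0.60),
    intergenic_transcript_unit = c(0.30, 0.30, 0.50, 0.40, 0.50, 0.40, 0.30, 0.30, 0.20, 0.30, 0.40, 0.40))
  colnames(m) <- default_factors
  if (!identical(factors, default_factors)) {
    # custom factor lists get a generic declining profile per class
    m <- m[, rep_len(seq_len(ncol(m)), length(factors)), drop = FALSE]
    colnames(m) <- factors
  }
  m
}

default_mark_probs <- function() {
  m <- rbind(
    active_promoter            = c(0.20, 0.80, 1.00, 0.90, 0.80, 1.00, 0.00, 1.00, 0.00, 0.95),
    silent_promoter            = c(0.30, 0.50, 0.70, 0.10, 0.10, 0.00, 0.90, 0.00, 0.00, 0.60),
    genic_enhancer             = c(0.90, 0.40, 0.00, 0.50, 0.30, 0.00, 0.10, 0.00, 0.00, 0.90),
    intergenic_enhancer        = c(0.90, 0.30, 0.00, 0.40, 0.20, 0.00, 0.10, 0.00, 0.00, 0.85),
    intergenic_transcript_unit = c(0.30, 0.50, 0.80, 0.60, 0.50, 1.00, 0.00, 0.90, 0.50, 0.90))
  colnames(m) <- synthetic_marks
  m
}

default_mark_margins <- function() {
  c(H3K4me1 = 1000, H3K4me2 = 2000, H3K4me3 = 2000, H3K27ac = 500,
    H3K9ac = 500, H3K36me3 = 6000, H3K27me3 = 5000, PolII = 1000,
    PolIII = 200, OCR = 0)
}

#' Configuration of the synthetic genome
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: 2 chromosomes of 10 Mb, 200 genes, 500 planted elements across
#' the five classes, 12 factors (including the architectural pair
#' CTCF/Rad21), zero-inflated log-normal expression, no mark dropout and
#' a low uniform noise-peak rate.
#'
#' @param genome named chromosome lengths.
#' @param n_genes number of genes (split evenly across chromosomes).
#' @param element_counts named counts per element class (names among
#'   `active_promoter`, `silent_promoter`, `genic_enhancer`,
#'   `intergenic_enhancer`, `intergenic_transcript_unit`).
#' @param factors factor names.
#' @param composition class x factor matrix of per-element inclusion
#'   probabilities.
#' @param mark_probs class x mark matrix of domain-emission probabilities.
#' @param mark_margins named bp margins by which an emitted domain extends
#'   beyond its element on each side.
#' @param expression list(meanlog, sdlog, zero_fraction) of the
#'   zero-inflated log-normal expression model.
#' @param peak_length length-2 range (bp) of emitted peak lengths.
#' @param intensity,noise_intensity list(meanlog, sdlog) of log-normal
#'   ChIP tag intensities for element and noise peaks.
#' @param noise_rate_per_mb expected uniform noise peaks per Mb.
#' @param mark_dropout probability that an emitted mark domain is dropped.
#' @param seed mandatory integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(genome = c(chr1 = 10e6, chr2 = 10e6),
                             n_genes = 200L,
                             element_counts = c(active_promoter = 60L,
                                                silent_promoter = 40L,
                                                genic_enhancer = 120L,
                                                intergenic_enhancer = 200L,
                                                intergenic_transcript_unit = 80L),
                             factors = default_factors,
                             composition = default_composition(factors),
                             mark_probs = default_mark_probs(),
                             mark_margins = default_mark_margins(),
                             expression = list(meanlog = 2, sdlog = 1.2,
                                               zero_fraction = 0.3),
                             peak_length = c(150L, 400L),
                             intensity = list(meanlog = 3, sdlog = 0.8),
                             noise_intensity = list(meanlog = 2.2, sdlog = 0.8),
                             noise_rate_per_mb = 5,
                             mark_dropout = 0,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  genome <- genome(genome)
  counts <- setNames(integer(length(synthetic_classes)), synthetic_classes)
  counts[names(element_counts)] <- as.integer(element_counts)
  if (any(counts < 0)) stop("element counts must be >= 0")
  stopifnot(all(rownames(composition) == synthetic_classes),
            identical(colnames(composition), factors),
            all(composition >= 0 & composition <= 1),
            all(rownames(mark_probs) == synthetic_classes),
            identical(colnames(mark_probs), synthetic_marks),
            all(mark_probs >= 0 & mark_probs <= 1),
            mark_dropout >= 0, mark_dropout <= 1,
            expression$zero_fraction >= 0, expression$zero_fraction <= 1,
            noise_rate_per_mb >= 0)
  structure(list(genome = genome, n_genes = as.integer(n_genes),
                 element_counts = counts, factors = factors,
                 composition = composition, mark_probs = mark_probs,
                 mark_margins = mark_margins, expression = expression,
                 peak_length = as.integer(peak_length),
                 intensity = intensity, noise_intensity = noise_intensity,
                 noise_rate_per_mb = noise_rate_per_mb,
                 mark_dropout = mark_dropout, seed = as.integer(seed)),
            class = "synthetic_config")
}

# --- internal layout helpers -----------------------------------------------

# tandem gene layout from a fixed left margin; returns gene_table rows
place_genes <- function(config) {
  chroms <- names(config$genome)
  per <- diff(round(seq(0, config$n_genes, length.out = length(chroms) + 1)))
  rows <- list()
  gidx <- 0L
  for (ci in seq_along(chroms)) {
    pos <- 100000L
    for (i in seq_len(per[ci])) {
      len <- as.integer(round(runif(1, 15000, 40000)))
      gap <- as.integer(round(runif(1, 20000, 30000)))
      gidx <- gidx + 1L
      rows[[gidx]] <- list(id = sprintf("gene%04d", gidx),
                           chrom = chroms[ci],
                           strand = sample(c("+", "-"), 1L),
                           tx_start = pos, tx_end = pos + len)
      pos <- pos + len + gap
    }
    if (pos > config$genome[ci] * 0.7)
      stop("infeasible placement: genes exceed 70% of chromosome ",
           chroms[ci])
  }
  d <- do.call(rbind, lapply(rows, as.data.frame))
  d
}

random_exons <- function(tx_start, tx_end, k) {
  bounds <- round(seq(tx_start, tx_end, length.out = k + 1))
  es <- ee <- integer(k)
  for (j in seq_len(k)) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    len <- as.integer(round(runif(1, 150, min(1200, hi - lo))))
    s <- as.integer(lo + floor(runif(1) * (hi - lo - len + 1)))
    es[j] <- s; ee[j] <- s + len
  }
  list(starts = es, ends = ee)
}

#' Generate the synthetic dataset
#'
#' Deterministic given `config$seed`.  Elements never overlap and are
#' spaced so clusters from different elements never merge; intergenic
#' elements lie at least 50 kb from every gene.  Every non-noise peak lies
#' inside its element and is recorded in the ground-truth manifest.
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_dataset`: list with `peaks` (peak
#'   GRanges with `element_id`, NA for noise), `marks` (named list of
#'   GRanges), `genes` (a [gene_table()]), `genome`, `truth` (manifest
#'   data.frame) and `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  layout <- place_genes(config)
  n <- nrow(layout)
  ex <- lapply(seq_len(n), function(i)
    random_exons(layout$tx_start[i], layout$tx_end[i], sample(3:8, 1L)))
  expr <- ifelse(runif(n) < config$expression$zero_fraction, 0,
                 rlnorm(n, config$expression$meanlog, config$expression$sdlog))
  genes <- gene_table(layout$id, layout$chrom, layout$strand,
                      layout$tx_start, layout$tx_end,
                      lapply(ex, `[[`, "starts"), lapply(ex, `[[`, "ends"),
                      expr)
  expr_class <- classify_expression(genes)
  counts <- config$element_counts
  high <- genes$id[expr_class == "high"]
  zero <- genes$id[expr_class == "zero"]
  if (length(high) < counts["active_promoter"])
    stop("infeasible placement: only ", length(high),
         " transcribed genes for ", counts["active_promoter"],
         " active promoter elements")
  if (length(zero) < counts["silent_promoter"])
    stop("infeasible placement: only ", length(zero),
         " silent genes for ", counts["silent_promoter"],
         " silent promoter elements")

  el <- list()  # rows: element_id, class, chrom, start, end, gene_id
  add <- function(class, chrom, s0, e0, gene_id = NA_character_) {
    el[[length(el) + 1L]] <<- data.frame(
      class = class, chrom = chrom, start = as.integer(s0),
      end = as.integer(e0), gene_id = gene_id)
  }
  gene_row <- function(id) genes[match(id, genes$id), , drop = FALSE]

  # promoter elements at host-gene TSSs
  for (cls in c("active_promoter", "silent_promoter")) {
    pool <- if (cls == "active_promoter") high else zero
    hosts <- sample(pool, counts[cls])
    for (id in hosts) {
      g <- gene_row(id)
      t0 <- tss(g)
      if (g$strand == "+") add(cls, g$chrom, t0 - 2000L, t0 + 200L, id)
      else add(cls, g$chrom, t0 - 200L, t0 + 2000L, id)
    }
  }

  # genic enhancers: inside a gene body, >= 10 kb downstream of the TSS
  if (counts["genic_enhancer"] > 0L) {
    if (counts["genic_enhancer"] > n)
      stop("infeasible placement: more genic enhancers than genes")
    hosts <- sample(genes$id, counts["genic_enhancer"])
    for (id in hosts) {
      g <- gene_row(id)
      elen <- as.integer(round(runif(1, 500, 1500)))
      dmax <- (g$tx_end - g$tx_start) - 1000L - elen
      d <- as.integer(round(runif(1, 10000, dmax)))
      if (g$strand == "+") add("genic_enhancer", g$chrom, g$tx_start + d,
                               g$tx_start + d + elen, id)
      else add("genic_enhancer", g$chrom, g$tx_end - d - elen,
               g$tx_end - d, id)
    }
  }

  # intergenic elements: in the gene-free tail of each chromosome,
  # >= 50 kb from genes, with >= 10 kb between consecutive elements
  n_int <- counts["intergenic_enhancer"] + counts["intergenic_transcript_unit"]
  if (n_int > 0L) {
    classes <- sample(rep(c("intergenic_enhancer",
                            "intergenic_transcript_unit"),
                          counts[c("intergenic_enhancer",
                                   "intergenic_transcript_unit")]))
    chroms <- names(config$genome)
    per <- diff(round(seq(0, n_int, length.out = length(chroms) + 1)))
    ci0 <- 0L
    for (ci in seq_along(chroms)) {
      gene_end <- max(0L, genes$tx_end[genes$chrom == chroms[ci]])
      zone <- c(gene_end + 60000L, config$genome[ci] - 50000L)
      k <- per[ci]
      if (k == 0L) next
      spacing <- floor((zone[2] - zone[1]) / k)
      max_elen <- 10000L
      if (spacing < max_elen + 12000L)
        stop("infeasible placement: intergenic zone on ", chroms[ci],
             " too small for ", k, " elements")
      for (i in seq_len(k)) {
        cls <- classes[ci0 + i]
        elen <- if (cls == "intergenic_transcript_unit")
          as.integer(round(runif(1, 2000, 10000)))
        else as.integer(round(runif(1, 500, 1500)))
        slack <- spacing - elen - 10000L
        s0 <- zone[1] + (i - 1L) * spacing +
          as.integer(floor(runif(1) * slack))
        add(cls, chroms[ci], s0, s0 + elen)
      }
      ci0 <- ci0 + k
    }
  }

  elements <- do.call(rbind, el)
  elements$element_id <- sprintf("el%04d", seq_len(nrow(elements)))

  # peaks per element, by class composition probabilities
  pk_rows <- list()
  emitted_marks <- character(nrow(elements))
  n_el_peaks <- integer(nrow(elements))
  for (i in seq_len(nrow(elements))) {
    cls <- elements$class[i]
    present <- config$factors[runif(length(config$factors)) <
                                config$composition[cls, ]]
    n_el_peaks[i] <- length(present)
    if (length(present)) {
      win_end <- min(elements$start[i] + 2500L, elements$end[i])
      for (f in present) {
        plen <- as.integer(round(runif(1, config$peak_length[1],
                                       config$peak_length[2])))
        plen <- min(plen, win_end - elements$start[i])
        s0 <- elements$start[i] +
          as.integer(floor(runif(1) * (win_end - elements$start[i] - plen + 1)))
        pk_rows[[length(pk_rows) + 1L]] <- data.frame(
          chrom = elements$chrom[i], start = s0, end = s0 + plen,
          factor = f,
          intensity = rlnorm(1, config$intensity$meanlog,
                             config$intensity$sdlog),
          element_id = elements$element_id[i])
      }
    }
    # mark domains, with dropout
    p <- config$mark_probs[cls, ] * (1 - config$mark_dropout)
    emit <- synthetic_marks[runif(length(synthetic_marks)) < p]
    emitted_marks[i] <- paste(emit, collapse = ",")
  }
  elements$n_peaks <- n_el_peaks
  elements$marks <- emitted_marks

  # noise peaks, uniform over the genome
  n_noise <- stats::rpois(1, config$noise_rate_per_mb *
                            sum(config$genome) / 1e6)
  if (n_noise > 0L) {
    chr <- sample(names(config$genome), n_noise, replace = TRUE,
                  prob = config$genome / sum(config$genome))
    plen <- as.integer(round(runif(n_noise, config$peak_length[1],
                                   config$peak_length[2])))
    s0 <- as.integer(floor(runif(n_noise) * (config$genome[chr] - plen)))
    pk_rows[[length(pk_rows) + 1L]] <- data.frame(
      chrom = chr, start = s0, end = s0 + plen,
      factor = sample(config$factors, n_noise, replace = TRUE),
      intensity = rlnorm(n_noise, config$noise_intensity$meanlog,
                         config$noise_intensity$sdlog),
      element_id = NA_character_)
  }
  pk <- do.call(rbind, pk_rows)
  peak_gr <- peaks(granges0(pk$chrom, pk$start, pk$end,
                            genome = config$genome),
                   factor = pk$factor, intensity = pk$intensity,
                   source_id = sprintf("pk%05d", seq_len(nrow(pk))))
  mcols(peak_gr)$element_id <- pk$element_id
  peak_gr <- peak_gr[order(as.integer(seqnames(peak_gr)), start(peak_gr))]

  # mark tracks from the per-element emissions
  marks <- lapply(synthetic_marks, function(m) {
    has <- vapply(strsplit(elements$marks, ",", fixed = TRUE),
                  function(v) m %in% v, TRUE)
    if (!any(has)) return(GRanges())
    margin <- config$mark_margins[[m]]
    granges0(elements$chrom[has],
             pmax(elements$start[has] - margin, 0),
             pmin(elements$end[has] + margin,
                  unname(config$genome[elements$chrom[has]])))
  })
  names(marks) <- synthetic_marks

  truth <- elements[, c("element_id", "class", "chrom", "start", "end",
                        "gene_id", "n_peaks", "marks")]
  truth$expected_context <- c(active_promoter = "promoter",
                              silent_promoter = "promoter",
                              genic_enhancer = "gene",
                              intergenic_enhancer = "intergenic",
                              intergenic_transcript_unit = "intergenic")[truth$class]
  truth$expected_class <- ifelse(
    truth$class %in% c("active_promoter", "intergenic_transcript_unit"),
    "transcript", "enhancer")
  rownames(truth) <- NULL

  structure(list(peaks = peak_gr, marks = marks, genes = genes,
                 genome = config$genome, truth = truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(x$peaks), "peaks (",
      sum(is.na(mcols(x$peaks)$element_id)), "noise ),",
      nrow(x$truth), "elements,", nrow(x$genes), "genes\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Write the synthetic dataset in pipeline input formats
#'
#' Emits one BED5 peak file per factor, one BED3 file per mark, a
#' refGene-like gene table, a two-column expression table, a chrom.sizes
#' file and the ground-truth manifest.
#'
#' @param sim a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "marks"), showWarnings = FALSE)
  paths <- list(peaks = character(0), marks = character(0))
  for (f in sort(unique(mcols(sim$peaks)$factor))) {
    sub <- sim$peaks[mcols(sim$peaks)$factor == f]
    mcols(sub)$name <- mcols(sub)$factor
    mcols(sub)$score <- mcols(sub)$intensity
    p <- file.path(dir, "peaks", paste0(f, ".bed"))
    write_bed(sub, p)
    paths$peaks[f] <- p
  }
  for (m in names(sim$marks)) {
    p <- file.path(dir, "marks", paste0(m, ".bed"))
    write_bed(sim$marks[[m]], p)
    paths$marks[m] <- p
  }
  paths$genes <- write_genes(sim$genes, file.path(dir, "genes.tsv"))
  paths$expression <- write_expression(sim$genes,
                                       file.path(dir, "expression.tsv"))
  paths$chrom_sizes <- write_chrom_sizes(sim$genome,
                                         file.path(dir, "chrom.sizes"))
  paths$manifest <- write_manifest(sim$truth, file.path(dir, "manifest.tsv"))
  invisible(paths)
}

manifest_columns <- c("element_id", "class", "chrom", "start", "end",
                      "gene_id", "n_peaks", "marks", "expected_context",
                      "expected_class")

#' Write / read the ground-truth manifest
#'
#' Tab-separated with header; round-trips losslessly.
#'
#' @param truth manifest data.frame (from `generate_synthetic()$truth`).
#' @param path file path.
#' @return `path` invisibly (write); the manifest data.frame (read).
#' @export
write_manifest <- function(truth, path) {
  stopifnot(identical(names(truth), manifest_columns))
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = c("character", "character", "character",
                                 "integer", "integer", "character",
                                 "integer", "character", "character",
                                 "character"),
                  na.strings = "NA")
  d$marks[is.na(d$marks)] <- ""
  d
}
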