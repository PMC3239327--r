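# End-to-end orchestration: read tracks, build clusters and the shuffle
# null, annotate, classify, compose, cover, and write every summary table
# plus a machine-readable run log.  All randomness flows from the single
# seed in the config; outputs carry no timestamps, so a rerun with the
# same config and seed is byte-identical.

#' Pipeline run configuration
#'
#' Defaults are the standard analysis constants: 2,000-bp peak extension,
#' cluster size limit 2, mappability 0.88, -2,000/+200 promoters, 10-kb
#' upstream gene windows, 5,000-bp domain splitting, 600-bp OCR merging,
#' 100 coverage orders, 20 intensity bins, and CTCF/Rad21 excluded from
#' transcript/enhancer classification.
#'
#' @param peak_files named character vector of per-factor BED5 peak files
#'   (names = factor names).
#' @param mark_files named character vector of per-mark BED3 domain files.
#' @param genes_file refGene-like gene table (see [read_genes()]).
#' @param expression_file optional two-column expression table.
#' @param chrom_sizes chrom.sizes path.
#' @param outdir output directory.
#' @param extension_length,min_cluster_size,mappability see
#'   [cluster_config()].
#' @param promoter_upstream,promoter_downstream promoter window (bp).
#' @param upstream_gene_limit upstream extent of the gene window (bp).
#' @param domain_max_length maximum split-domain length (bp).
#' @param ocr_merge_gap gap within which OCR regions are merged (bp).
#' @param n_coverage_orders shuffled factor orders per coverage curve.
#' @param n_intensity_bins intensity quantile bins per factor dataset.
#' @param exclude_factors factors excluded from classification (and from
#'   the mark-overlap variant).
#' @param seed integer seed.
#' @return a `run_config` list.
#' @export
run_config <- function(peak_files, mark_files, genes_file,
                       expression_file = NULL, chrom_sizes, outdir,
                       extension_length = 2000L, min_cluster_size = 2L,
                       mappability = 0.88,
                       promoter_upstream = 2000L, promoter_downstream = 200L,
                       upstream_gene_limit = 10000L,
                       domain_max_length = 5000L, ocr_merge_gap = 600L,
                       n_coverage_orders = 100L, n_intensity_bins = 20L,
                       exclude_factors = c("CTCF", "Rad21"), seed = 1L) {
  cfg <- list(peak_files = peak_files, mark_files = mark_files,
              genes_file = genes_file, expression_file = expression_file,
              chrom_sizes = chrom_sizes, outdir = outdir,
              extension_length = as.integer(extension_length),
              min_cluster_size = as.integer(min_cluster_size),
              mappability = mappability,
              promoter_upstream = as.integer(promoter_upstream),
              promoter_downstream = as.integer(promoter_downstream),
              upstream_gene_limit = as.integer(upstream_gene_limit),
              domain_max_length = as.integer(domain_max_length),
              ocr_merge_gap = as.integer(ocr_merge_gap),
              n_coverage_orders = as.integer(n_coverage_orders),
              n_intensity_bins = as.integer(n_intensity_bins),
              exclude_factors = exclude_factors,
              seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the [run_config()] arguments; `peak_files` and
#' `mark_files` are maps from factor/mark name to path.  Relative paths
#' resolve against the YAML file's directory.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  y$peak_files <- setNames(fix(unlist(y$peak_files)), names(unlist(y$peak_files)))
  y$mark_files <- setNames(fix(unlist(y$mark_files)), names(unlist(y$mark_files)))
  for (k in c("genes_file", "expression_file", "chrom_sizes"))
    if (!is.null(y[[k]])) y[[k]] <- fix(y[[k]])
  args <- utils::modifyList(y, list(...))
  do.call(run_config, args)
}

pipeline_stages <- c("cluster", "annotate", "classify", "compose",
                     "coverage")

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

cluster_table <- function(regions) {
  data.frame(chrom = as.character(seqnames(regions)),
             start = start0(regions), end = end0(regions),
             size = mcols(regions)$size, factors = mcols(regions)$factors,
             peak_ids = mcols(regions)$peak_ids)
}

#' Run the full analysis
#'
#' Executes the requested stages in order (each stage implies its
#' predecessors), writes every summary table under `config$outdir`, and
#' finishes with `run_log.yaml` recording the seed, all parameters and
#' per-stage input/output counts.  A stage failure aborts with the stage
#' name.
#'
#' @param config a [run_config()].
#' @param stages subset of `c("cluster","annotate","classify","compose",
#'   "coverage")`; default all.
#' @return invisibly, a list with the in-memory stage results and the
#'   written file paths.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  last <- max(match(stages, pipeline_stages))
  run_stages <- pipeline_stages[seq_len(last)]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list(config = config, paths = character(0))
  log <- list(seed = config$seed,
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              parameters = config[setdiff(names(config),
                                          c("peak_files", "mark_files"))],
              stages = list())
  log$parameters$outdir <- NULL
  emit <- function(name, d) {
    p <- write_tsv(d, file.path(config$outdir, paste0(name, ".tsv")))
    out$paths[name] <<- p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- inputs ---------------------------------------------------------------
  gnm <- stage("input", read_chrom_sizes(config$chrom_sizes))
  pk <- stage("input", {
    lst <- lapply(names(config$peak_files), function(f)
      read_peaks(config$peak_files[[f]], factor = f, genome = gnm))
    do.call(c, lst)
  })
  marks <- stage("input", {
    trk <- lapply(names(config$mark_files), function(m)
      read_bed(config$mark_files[[m]], label = m, genome = gnm))
    names(trk) <- names(config$mark_files)
    if ("OCR" %in% names(trk))
      trk$OCR <- merge_within_gap(trk$OCR, config$ocr_merge_gap)
    mark_library(trk, max_len = config$domain_max_length)
  })
  genes_all <- stage("input", read_genes(config$genes_file,
                                         config$expression_file))
  genes <- select_nonredundant(genes_all)
  expr_class <- classify_expression(genes)
  log$stages$input <- list(n_peaks = length(pk),
                           n_factors = length(unique(mcols(pk)$factor)),
                           n_marks = length(marks$full),
                           n_genes = nrow(genes_all),
                           n_nonredundant = nrow(genes))

  ccfg <- cluster_config(config$extension_length, config$min_cluster_size,
                         config$mappability)

  # H3K4me union and acetylation union at split resolution, when present
  split_union <- function(names_) {
    have <- intersect(names_, names(marks$split))
    if (!length(have)) return(GRanges())
    merge_overlapping(do.call(c, unname(marks$split[have])))
  }
  k4me_union <- split_union(c("H3K4me1", "H3K4me2", "H3K4me3"))

  # -- stage: cluster -------------------------------------------------------
  cs <- NULL
  if ("cluster" %in% run_stages) {
    cs <- stage("cluster", build_clusters(pk, ccfg, gnm))
    shuffled <- stage("cluster",
                      shuffle_peaks(pk, gnm, config$mappability,
                                    seed = config$seed))
    cs_null <- stage("cluster", build_clusters(shuffled, ccfg, gnm))
    emit("clusters", cluster_table(cs$clusters))
    emit("singletons", cluster_table(cs$singletons))
    h_real <- cluster_size_histogram(cs)
    h_null <- cluster_size_histogram(cs_null)
    len_real <- mean_length_by_size(cs)
    len_null <- mean_length_by_size(cs_null)
    sizes <- sort(unique(as.integer(c(names(h_real), names(h_null)))))
    at <- function(v, s) ifelse(is.na(v[as.character(s)]), 0,
                                v[as.character(s)])
    emit("shuffle_comparison",
         data.frame(size = sizes,
                    real_count = as.integer(at(h_real, sizes)),
                    shuffled_count = as.integer(at(h_null, sizes)),
                    real_mean_length = round(at(len_real, sizes), 2),
                    shuffled_mean_length = round(at(len_null, sizes), 2)))
    # intensity bins: singleton vs cluster member peaks per bin, pooled
    member_idx <- unlist(cs$members, use.names = FALSE)
    bin_by_peak <- integer(length(pk))
    for (i in split(seq_along(pk), mcols(pk)$factor))
      bin_by_peak[i] <- as.integer(bin_peaks_by_intensity(
        pk[i], config$n_intensity_bins))
    in_cluster <- seq_along(pk) %in% member_idx
    emit("intensity_bins",
         data.frame(bin = seq_len(config$n_intensity_bins),
                    singleton_peaks = vapply(seq_len(config$n_intensity_bins),
                                             function(b) sum(!in_cluster & bin_by_peak == b), 0L),
                    cluster_peaks = vapply(seq_len(config$n_intensity_bins),
                                           function(b) sum(in_cluster & bin_by_peak == b), 0L)))
    # mark overlap of clusters (with and without excluded factors)
    overlap_row <- function(set, variant) {
      data.frame(variant = variant,
                 H3K4me = overlap_fraction(set$clusters, k4me_union),
                 OCR = if (!is.null(marks$split$OCR))
                   overlap_fraction(set$clusters, marks$split$OCR) else NA,
                 acetyl = overlap_fraction(set$clusters,
                                           split_union(c("H3K27ac", "H3K9ac"))))
    }
    pk_noexcl <- pk[!(mcols(pk)$factor %in% config$exclude_factors)]
    cs_noexcl <- stage("cluster", build_clusters(pk_noexcl, ccfg, gnm))
    emit("mark_overlap", rbind(overlap_row(cs, "all_factors"),
                               overlap_row(cs_noexcl, "excluded_removed")))
    out$clusters <- cs
    out$null <- cs_null
    log$stages$cluster <- list(n_clusters = length(cs$clusters),
                               n_singletons = length(cs$singletons),
                               n_clusters_shuffled = length(cs_null$clusters))
  }

  # -- stage: annotate ------------------------------------------------------
  ctx <- NULL
  if ("annotate" %in% run_stages) {
    ctx <- stage("annotate",
                 assign_gene_context(cs$clusters, genes,
                                     config$promoter_upstream,
                                     config$promoter_downstream,
                                     config$upstream_gene_limit, gnm))
    emit("gene_context",
         cbind(cluster_table(cs$clusters)[, c("chrom", "start", "end", "size")],
               ctx,
               expression_class = ifelse(is.na(ctx$gene_id), NA,
                                         unname(expr_class[ctx$gene_id]))))
    profs <- lapply(c(high = "high", zero = "zero"), function(cl)
      stage("annotate", tss_profile(cs$clusters,
                                    genes[expr_class[genes$id] == cl, ],
                                    window = 10000L, bin = 200L)))
    emit("tss_profiles",
         data.frame(bin = names(profs$high),
                    transcribed = as.integer(profs$high),
                    silent = as.integer(profs$zero)))
    out$context <- ctx
    log$stages$annotate <- as.list(table(ctx$context))
  }

  # -- stage: classify ------------------------------------------------------
  cls <- NULL
  if ("classify" %in% run_stages) {
    cls <- stage("classify",
                 classify_clusters(cs, marks, config$exclude_factors))
    emit("classification",
         cbind(cluster_table(cs$clusters[cls$cluster])[, c("chrom", "start",
                                                           "end", "size")],
               cls[, c("class", "provenance")]))
    xt <- stage("classify", cross_tabulate(cls, ctx, expr_class))
    emit("cross_tab_annotation", as.data.frame(xt$by_annotation))
    emit("cross_tab_expression", as.data.frame(xt$by_expression))
    enh_idx <- cls$cluster[cls$class == "enhancer" &
                             ctx$context[cls$cluster] == "intergenic"]
    enh_markers <- intersect(c("H3K4me1", "H3K4me3", "H3K27ac", "H3K9ac",
                               "OCR"), names(marks$split))
    emit("enhancer_marker_overlap",
         data.frame(marker = enh_markers,
                    fraction = unname(enhancer_marker_overlap(
                      cs$clusters[enh_idx], marks, enh_markers))))
    both <- c(granges(cs$clusters), granges(cs$singletons))
    emit("redundancy",
         data.frame(mark = names(marks$split),
                    ratio_clusters = vapply(marks$split, redundancy_ratio,
                                            numeric(1),
                                            regions = granges(cs$clusters)),
                    ratio_with_singletons = vapply(marks$split,
                                                   redundancy_ratio,
                                                   numeric(1),
                                                   regions = both)))
    out$classes <- cls
    log$stages$classify <- as.list(table(cls$class))
  }

  # -- stage: compose -------------------------------------------------------
  if ("compose" %in% run_stages) {
    factors <- sort(unique(mcols(pk)$factor))
    k4_hit <- countOverlaps(cs$clusters, k4me_union,
                            ignore.strand = TRUE) > 0L
    ecl <- ifelse(is.na(ctx$gene_id), NA, unname(expr_class[ctx$gene_id]))
    groups <- list(
      `prom-h` = which(ctx$context == "promoter" & ecl == "high"),
      `prom-z` = which(ctx$context == "promoter" & ecl == "zero"),
      `gene-pos-h` = which(ctx$context == "gene" & ecl == "high" & k4_hit),
      `gene-pos-z` = which(ctx$context == "gene" & ecl == "zero" & k4_hit),
      `gene-neg-h` = which(ctx$context == "gene" & ecl == "high" & !k4_hit),
      `gene-neg-z` = which(ctx$context == "gene" & ecl == "zero" & !k4_hit))
    groups$`gene-any-h` <- sort(c(groups$`gene-pos-h`, groups$`gene-neg-h`))
    groups$`gene-any-z` <- sort(c(groups$`gene-pos-z`, groups$`gene-neg-z`))
    vecs <- lapply(groups, function(i)
      stage("compose", composition_vector(cs, factors, subset = i)))
    emit("composition_vectors",
         cbind(data.frame(factor = factors),
               as.data.frame(lapply(vecs, function(v) round(unname(v), 4)),
                             check.names = FALSE)))
    nm <- names(groups)
    cormat <- matrix(NA_real_, length(nm), length(nm),
                     dimnames = list(nm, nm))
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      ok <- attr(vecs[[i]], "n_clusters") > 0 &&
        attr(vecs[[j]], "n_clusters") > 0 &&
        stats::sd(vecs[[i]]) > 0 && stats::sd(vecs[[j]]) > 0
      if (ok) cormat[i, j] <- round(pearson_r(vecs[[i]], vecs[[j]]), 4)
    }
    emit("composition_correlations",
         cbind(data.frame(group = nm),
               as.data.frame(cormat, check.names = FALSE)))
    out$composition <- vecs
    log$stages$compose <- lapply(groups, length)
  }

  # -- stage: coverage ------------------------------------------------------
  if ("coverage" %in% run_stages) {
    proms <- promoter_intervals(genes, config$promoter_upstream,
                                config$promoter_downstream, gnm)
    curves <- list()
    for (cl in c("high", "medium_low", "zero")) {
      tg <- proms[expr_class[genes$id] == cl]
      if (length(tg) == 0L) next
      for (variant in c("clusters", "with_singletons")) {
        curves[[paste(cl, variant, sep = ".")]] <- stage(
          "coverage",
          coverage_curve(tg, cs, n_orders = config$n_coverage_orders,
                         seed = config$seed,
                         include_singletons = variant == "with_singletons"))
      }
    }
    nf <- length(attr(curves[[1]], "factors"))
    emit("coverage_curves",
         cbind(data.frame(k = 0:nf),
               as.data.frame(lapply(curves, function(v)
                 round(as.numeric(v), 4)), check.names = FALSE)))
    out$coverage <- curves
    log$stages$coverage <- list(n_orders = config$n_coverage_orders,
                                n_curves = length(curves))
  }

  log_path <- file.path(config$outdir, "run_log.yaml")
  yaml::write_yaml(log, log_path)
  out$paths["run_log"] <- log_path
  out$log <- log
  invisible(out)
}
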