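#' Read / write CpG methylation call tables
#'
#' The coverage-table format is tab-separated `chrom  pos  meth  unmeth` with a
#' header, positions 1-based (the CpG cytosine). `read_cpg_calls()` reads one
#' file (one cell); `read_cpg_dir()` reads every `*.tsv` in a directory,
#' taking cell ids from file names. `write_cpg_calls()` writes one file per
#' cell into `dir`.
#'
#' @param path file path.
#' @param cell cell id to attach (default: file name without extension).
#' @return A tibble `cell`, `chrom`, `pos`, `meth`, `unmeth`.
#' @export
read_cpg_calls <- function(path, cell = NULL) {
  # parsing problems are re-raised as errors below, so silence readr's note
  x <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      chrom = readr::col_character(),
                      pos = readr::col_integer(),
                      meth = readr::col_integer(),
                      unmeth = readr::col_integer())))
  pr <- readr::problems(x)
  if (nrow(pr) > 0L) {
    stop_trio("malformed line ", pr$row[1] + 1L, " in ", path)
  }
  check_columns(x, c("chrom", "pos", "meth", "unmeth"), path)
  if (nrow(x) > 0L) {
    if (anyNA(x)) {
      stop_trio("missing value at line ",
                which(!complete.cases(x))[1] + 1L, " in ", path)
    }
    if (any(x$meth < 0 | x$unmeth < 0)) stop_trio("negative count in ", path)
    if (any(x$meth + x$unmeth == 0)) {
      stop_trio("zero-depth CpG record in ", path)
    }
  }
  dplyr::mutate(x,
                cell = cell %||% sub("\\.[^.]*$", "", basename(path)),
                .before = 1)
}

#' @rdname read_cpg_calls
#' @param dir directory of per-cell `*.tsv` files.
#' @export
read_cpg_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop_trio("no .tsv files in ", dir)
  purrr::map_dfr(files, read_cpg_calls)
}

#' @rdname read_cpg_calls
#' @param calls tibble with `cell`, `chrom`, `pos`, `meth`, `unmeth`.
#' @export
write_cpg_calls <- function(calls, dir) {
  check_columns(calls, c("cell", "chrom", "pos", "meth", "unmeth"), "calls")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in unique(calls$cell)) {
    readr::write_tsv(
      calls[calls$cell == cl, c("chrom", "pos", "meth", "unmeth")],
      file.path(dir, paste0(cl, ".tsv")))
  }
  invisible(dir)
}

#' Read / write gene expression tables
#'
#' Wide TSV: first column `gene_id`, one FPKM column per cell. Duplicate gene
#' ids and missing values are errors.
#'
#' @param path file path.
#' @return Long tibble `gene_id`, `cell`, `fpkm`.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(x, "gene_id", path)
  if (anyDuplicated(x$gene_id)) {
    stop_trio("duplicate gene id in ", path, ": ",
              x$gene_id[duplicated(x$gene_id)][1])
  }
  long <- tidyr::pivot_longer(x, -"gene_id", names_to = "cell",
                              values_to = "fpkm")
  if (anyNA(long$fpkm) || any(!is.finite(long$fpkm))) {
    stop_trio("missing or non-finite FPKM value in ", path)
  }
  if (any(long$fpkm < 0)) stop_trio("negative FPKM in ", path)
  dplyr::arrange(long, .data$gene_id, .data$cell)
}

#' @rdname read_expression
#' @param expr long tibble `gene_id`, `cell`, `fpkm`.
#' @export
write_expression <- function(expr, path) {
  check_columns(expr, c("gene_id", "cell", "fpkm"), "expr")
  wide <- tidyr::pivot_wider(expr, names_from = "cell", values_from = "fpkm")
  readr::write_tsv(dplyr::arrange(wide, .data$gene_id), path)
  invisible(path)
}

#' Read / write BED interval files
#'
#' Standard 3+ column BED: 0-based half-open intervals, optional `name`,
#' `score`, `strand` columns. Input may be unsorted; output is sorted by
#' chromosome and start. Records with `end <= start` are rejected.
#'
#' @param path file path.
#' @return Tibble `chrom`, `start`, `end` (+ `name`, `score`, `strand` when
#'   present).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand")[1:max(
                                         utils::count.fields(path, sep = "\t"))])
  x <- tibble::as_tibble(x)
  if (any(x$end <= x$start)) {
    stop_trio("interval with end <= start in ", path)
  }
  dplyr::arrange(x, .data$chrom, .data$start)
}

#' @rdname read_bed
#' @param intervals tibble with at least `chrom`, `start`, `end`.
#' @export
write_bed <- function(intervals, path) {
  check_columns(intervals, c("chrom", "start", "end"), "intervals")
  if (any(intervals$end <= intervals$start)) {
    stop_trio("interval with end <= start")
  }
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  out <- dplyr::arrange(intervals[, cols], .data$chrom, .data$start)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Reads (or builds) the run configuration for [run_pipeline()]: annotation
#' geometry, simulator parameters, analysis thresholds, and the seed. Unknown
#' keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path YAML file; keys mirror the arguments of
#'   [simulate_annotation()], [sim_config()] and the analysis thresholds
#'   (`min_depth`, `min_cpgs_region`, `min_cpgs_cgi`, `min_diff`, `alpha`,
#'   `alpha_fdr`, `top_n`, `sigma`, `stay_prob`, `mask_frac`, `half_window`,
#'   `expr_threshold`, `var_window`, `k_clusters`, `seed`).
#' @return A named list of class `trio_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

#' @rdname read_run_config
#' @param ... configuration values overriding the defaults.
#' @export
run_config <- function(...) build_run_config(list(...))

run_config_defaults <- function() {
  list(seed = 1,
       annotation = list(n_chrom = 10, chrom_size = 4e7, bin_size = 1e7,
                         frags_per_bin = 1200, genes_per_bin = 25,
                         gene_length = 2e4, cgi_fraction = 0.7,
                         include_x = FALSE),
       simulation = list(),
       min_depth = 3, min_cpgs_region = 6, min_cpgs_cgi = 5,
       min_diff = 0.3, alpha = 0.05, alpha_fdr = 0.05, top_n = 300,
       sigma = 0.4, stay_prob = 1 - 1e-4, mask_frac = 0.1,
       half_window = 50, expr_threshold = 1.5, var_window = 3000,
       k_clusters = 2)
}

build_run_config <- function(values) {
  defaults <- run_config_defaults()
  unknown <- setdiff(names(values), names(defaults))
  if (length(unknown) > 0L) {
    stop_trio("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (section in c("annotation", "simulation")) {
    if (!is.null(values[[section]])) {
      allowed <- if (section == "annotation") {
        names(formals(simulate_annotation))
      } else {
        names(formals(sim_config))
      }
      bad <- setdiff(names(values[[section]]), allowed)
      if (length(bad) > 0L) {
        stop_trio("unknown ", section, " key(s): ", paste(bad, collapse = ", "))
      }
      defaults[[section]] <- utils::modifyList(defaults[[section]],
                                               values[[section]])
      values[[section]] <- NULL
    }
  }
  structure(utils::modifyList(defaults, values), class = "trio_run_config")
}

#' Run the full synthetic triple-omics pipeline
#'
#' Simulates a population with known truth, then runs every analysis arm:
#' read-depth CNV (normalization, HMM fitting, clustering, accuracy against
#' truth), expression CNV (moving average, window aggregation, clustering),
#' methylome summaries (filters, promoter / gene-body levels,
#' methylation-expression correlations, metagene profile), heterogeneity
#' ranking, and subpopulation comparisons (dmCGIs, differential expression,
#' PCA, per-cell copy-expression and copy-methylation correlations). Inputs,
#' result tables, a machine-readable `summary.json`, and a run log are
#' written under `out_dir`; reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config a `trio_run_config` (see [run_config()]); a path to a YAML
#'   file is also accepted.
#' @param out_dir output directory.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "trio_run_config"))
  problems <- character(0)
  if (missing(out_dir) || !is.character(out_dir)) {
    problems <- c(problems, "out_dir must be a path")
  }
  if (length(problems) > 0L) {
    stop_trio("invalid pipeline invocation: ", paste(problems, collapse = "; "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ann <- do.call(simulate_annotation,
                 c(config$annotation, list(seed = config$seed)))
  sim_cfg <- do.call(sim_config, config$simulation)
  sim <- simulate_population(sim_cfg, ann, seed = config$seed + 1)
  truth <- sim$truth

  write_truth(truth, file.path(out_dir, "truth"))
  write_cpg_calls(sim$calls, file.path(out_dir, "calls"))
  write_expression(sim$expression, file.path(out_dir, "expression.tsv"))

  # ---- read-depth CNV ----------------------------------------------------
  bins <- count_fragments_per_bin(ann$fragments, ann$bins, unique_only = TRUE)
  bins <- mask_low_coverage_bins(bins, config$mask_frac)
  factors <- normalization_factors(sim$control, bins)
  values <- normalize_bins(sim$bin_depth, factors)
  fit <- fit_cnv_hmm(values, bins, sigma = config$sigma,
                     stay_prob = config$stay_prob)
  prof <- fit$profile
  readr::write_tsv(prof, file.path(out_dir, "cnv_rrbs_profile.tsv"))
  acc <- dplyr::inner_join(prof[!prof$masked, ],
                           truth$cnv_truth, by = c("cell", "bin_id"))
  state_accuracy <- mean(acc$state == acc$copy, na.rm = TRUE)
  clust_rrbs <- cluster_cells(values, k = config$k_clusters)
  lab <- dplyr::inner_join(clust_rrbs$labels, truth$cells, by = "cell")
  ari_rrbs <- ari(lab$cluster, lab$subpop)

  # ---- expression CNV ----------------------------------------------------
  wexpr <- expression_cnv(sim$expression, sim$reference, ann$genes, ann$bins,
                          threshold = config$expr_threshold,
                          half_window = config$half_window)
  readr::write_tsv(wexpr, file.path(out_dir, "cnv_rna_windows.tsv"))
  clust_rna <- cluster_cells(wexpr, k = config$k_clusters)
  lab2 <- dplyr::inner_join(clust_rna$labels, truth$cells, by = "cell")
  ari_rna <- ari(lab2$cluster, lab2$subpop)
  ari_cross <- ari(clust_rrbs$labels$cluster[
    match(clust_rna$labels$cell, clust_rrbs$labels$cell)],
    clust_rna$labels$cluster)

  # ---- methylome ---------------------------------------------------------
  fcalls <- filter_cpg_calls(sim$calls, min_depth = config$min_depth)
  prom <- promoter_regions(ann$genes, sizes = ann$chrom_sizes)
  body <- gene_body_regions(ann$genes, ann$cgis)
  prom_meth <- region_methylation(fcalls, prom,
                                  min_cpgs = config$min_cpgs_region)
  body_meth <- region_methylation(fcalls, body,
                                  min_cpgs = config$min_cpgs_region)
  expr_cells <- sim$expression
  r_prom <- methylation_expression_cor(prom_meth, expr_cells)
  r_body <- methylation_expression_cor(body_meth, expr_cells)
  meta <- metagene_profile(fcalls, ann$genes)
  readr::write_tsv(meta, file.path(out_dir, "metagene_profile.tsv"))
  glob <- global_methylation(fcalls)

  # ---- heterogeneity -----------------------------------------------------
  wins <- tile_windows(ann$chrom_sizes, config$var_window)
  wstats <- window_cell_stats(fcalls, wins)
  wvar <- window_variance(wstats)
  topw <- rank_variable_windows(wvar, wins, config$top_n)
  readr::write_tsv(topw, file.path(out_dir, "variable_windows.tsv"))
  enr <- element_enrichment(topw, dplyr::inner_join(
    wvar, wins, by = "window_id"), list(cgi = ann$cgis))

  # ---- subpopulation differences ----------------------------------------
  labels <- truth$cells
  pooled <- pool_cgi_counts(fcalls, ann$cgis, labels,
                            min_cpgs = config$min_cpgs_cgi)
  dmcgi <- call_dmcgi(pooled, min_diff = config$min_diff,
                      alpha = config$alpha)
  readr::write_tsv(dmcgi, file.path(out_dir, "dmcgi.tsv"))
  de <- differential_expression(sim$expression, labels,
                                alpha_fdr = config$alpha_fdr)
  readr::write_tsv(de, file.path(out_dir, "differential_expression.tsv"))
  pca <- pca_cells(sim$expression)
  readr::write_tsv(pca$coords, file.path(out_dir, "pca_coords.tsv"))
  states <- prof[!prof$masked & !is.na(prof$state),
                 c("cell", "bin_id", "state")]
  r_ce <- suppressWarnings(copy_expression_cor(states, wexpr))
  wmeth <- window_methylation(fcalls, ann$bins)
  r_cm <- suppressWarnings(copy_methylation_cor(states, wmeth))

  summary <- list(
    seed = config$seed,
    n_cells = nrow(truth$cells),
    n_cpg_calls = nrow(sim$calls),
    cnv_rrbs = list(state_accuracy = round(state_accuracy, 6),
                    clustering_ari = round(ari_rrbs, 6)),
    cnv_rna = list(clustering_ari = round(ari_rna, 6),
                   cross_modality_ari = round(ari_cross, 6)),
    methylome = list(
      global_level = round(mean(glob$level), 6),
      promoter_expression_r = round(mean(r_prom$r, na.rm = TRUE), 6),
      gene_body_expression_r = round(mean(r_body$r, na.rm = TRUE), 6),
      tss_level = round(mean(meta$level[meta$zone == "body"][1:2],
                             na.rm = TRUE), 6),
      mid_body_level = round(mean(meta$level[meta$zone == "body"][10:15],
                                  na.rm = TRUE), 6)),
    heterogeneity = list(n_ranked_windows = nrow(wvar),
                         cgi_enrichment_odds = round(enr$odds_ratio[1], 6),
                         cgi_enrichment_fdr = signif(enr$fdr[1], 6)),
    subpop = list(n_dmcgi = nrow(dmcgi),
                  n_de_up = sum(de$direction == "up", na.rm = TRUE),
                  n_de_down = sum(de$direction == "down", na.rm = TRUE),
                  copy_expression_r_mean = round(mean(r_ce$r, na.rm = TRUE), 6),
                  copy_expression_r_sd = round(sd(r_ce$r, na.rm = TRUE), 6),
                  copy_methylation_r_mean = round(mean(r_cm$r, na.rm = TRUE), 6),
                  copy_methylation_r_sd = round(sd(r_cm$r, na.rm = TRUE), 6)))
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, file.path(out_dir, "summary.json"))
  log_lines <- c(
    paste0("trioscope ", as.character(utils::packageVersion("trioscope"))),
    paste0("seed: ", config$seed),
    paste0("bins: ", nrow(ann$bins), " x ", config$annotation$bin_size, " bp"),
    paste0("cells: ", nrow(truth$cells)),
    paste0("parameters: sigma=", config$sigma, " stay_prob=", config$stay_prob,
           " min_depth=", config$min_depth, " min_diff=", config$min_diff,
           " alpha=", config$alpha, " top_n=", config$top_n))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(summary)
}
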