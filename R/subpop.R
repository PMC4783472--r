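#' Pool CpG-island methylation counts within subpopulations
#'
#' A CGI is qualified in a cell when at least `min_cpgs` confidently called
#' CpGs are detected in it; qualified cells' methylated / unmethylated site
#' counts are summed per subpopulation, but only for CGIs qualified in enough
#' cells of that subpopulation. The minimum is
#' `max(min_cells_abs, ceiling(min_cells_frac * n_cells))`, which with the
#' defaults gives 3 of 7 and 5 of 18 for subpopulations of those sizes.
#'
#' @param calls filtered binarized calls (`cell`, `chrom`, `pos`, `call`).
#' @param cgis CGI tibble `cgi_id`, `chrom`, `start`, `end`.
#' @param labels tibble `cell`, `subpop` (>= 2 subpopulations).
#' @param min_cpgs CpGs needed to qualify a CGI in a cell (default 5).
#' @param min_cells_abs,min_cells_frac absolute floor and fractional rule for
#'   the per-subpopulation minimum of qualified cells.
#' @return Tibble `cgi_id`, `subpop`, `mcg`, `umcg`, `n_qualified`,
#'   `qualified` (pooled rows only carry `qualified = TRUE`).
#' @export
pool_cgi_counts <- function(calls, cgis, labels, min_cpgs = 5,
                            min_cells_abs = 3, min_cells_frac = 0.25) {
  check_columns(calls, c("cell", "chrom", "pos", "call"), "calls")
  check_columns(labels, c("cell", "subpop"), "labels")
  if (length(unique(labels$subpop)) < 2L) {
    stop_trio("labels must define at least 2 subpopulations")
  }
  group_n <- dplyr::count(labels, .data$subpop, name = "n_cells")
  hits <- calls_in_regions(calls, cgis, "cgi_id")
  per_cell <- hits |>
    dplyr::group_by(cgi_id = .data$region_id, .data$cell) |>
    dplyr::summarise(mcg = sum(.data$call), umcg = sum(1 - .data$call),
                     n_cpgs = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_cpgs >= min_cpgs)
  pooled <- per_cell |>
    dplyr::inner_join(labels, by = "cell") |>
    dplyr::group_by(.data$cgi_id, .data$subpop) |>
    dplyr::summarise(mcg = sum(.data$mcg), umcg = sum(.data$umcg),
                     n_qualified = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(group_n, by = "subpop") |>
    dplyr::mutate(qualified = .data$n_qualified >=
                    pmax(min_cells_abs,
                         ceiling(min_cells_frac * .data$n_cells))) |>
    dplyr::select("cgi_id", "subpop", "mcg", "umcg", "n_qualified",
                  "qualified")
  dplyr::filter(pooled, .data$qualified)
}

#' Call differentially methylated CpG islands between two subpopulations
#'
#' For every CGI pooled in both subpopulations, computes methylation levels
#' `mCG / (mCG + umCG)`, tests the pooled 2x2 count table with a two-sided
#' Fisher's exact test, and emits the CGI when `p < alpha` and the absolute
#' level difference is at least `min_diff`. Direction reports which
#' subpopulation is hypermethylated.
#'
#' @param pooled output of [pool_cgi_counts()].
#' @param groups which two subpopulations to compare (default: the first two
#'   in the table, alphabetically).
#' @param min_diff minimum absolute methylation difference (default 0.3).
#' @param alpha significance level of the Fisher test (default 0.05).
#' @return Tibble `cgi_id`, `level_a`, `level_b`, `difference`, `p`,
#'   `direction` (one row per emitted dmCGI).
#' @export
call_dmcgi <- function(pooled, groups = NULL, min_diff = 0.3, alpha = 0.05) {
  check_columns(pooled, c("cgi_id", "subpop", "mcg", "umcg"), "pooled")
  groups <- groups %||% sort(unique(pooled$subpop))[1:2]
  if (length(groups) != 2L) stop_trio("need exactly two subpopulations")
  a <- dplyr::filter(pooled, .data$subpop == groups[1])
  b <- dplyr::filter(pooled, .data$subpop == groups[2])
  both <- dplyr::inner_join(a, b, by = "cgi_id", suffix = c("_a", "_b"))
  zero <- (both$mcg_a + both$umcg_a == 0) | (both$mcg_b + both$umcg_b == 0)
  if (any(zero)) {
    warn(paste0(sum(zero), " CGI(s) with an empty pool skipped"))
    both <- both[!zero, ]
  }
  if (nrow(both) == 0L) {
    return(tibble::tibble(cgi_id = character(), level_a = numeric(),
                          level_b = numeric(), difference = numeric(),
                          p = numeric(), direction = character()))
  }
  res <- both |>
    dplyr::rowwise() |>
    dplyr::mutate(
      level_a = .data$mcg_a / (.data$mcg_a + .data$umcg_a),
      level_b = .data$mcg_b / (.data$mcg_b + .data$umcg_b),
      difference = .data$level_a - .data$level_b,
      p = fisher.test(matrix(c(.data$mcg_a, .data$umcg_a,
                               .data$mcg_b, .data$umcg_b), nrow = 2))$p.value
    ) |>
    dplyr::ungroup()
  res <- dplyr::filter(res, .data$p < alpha,
                       abs(.data$difference) >= min_diff)
  res <- dplyr::mutate(res,
                       direction = ifelse(.data$difference > 0,
                                          paste0("hyper-", groups[1]),
                                          paste0("hyper-", groups[2])))
  dplyr::select(res, "cgi_id", "level_a", "level_b", "difference", "p",
                "direction")
}

#' Differential expression between two subpopulations
#'
#' Per-gene two-sided Wilcoxon rank-sum test on `log2(FPKM + 1)` with
#' Benjamini-Hochberg adjustment; genes constant across all cells get p = 1 by
#' convention. Genes with `q < alpha_fdr` are split by the sign of the median
#' difference (group a minus group b).
#'
#' @param expr long tibble `gene_id`, `cell`, `fpkm`.
#' @param labels tibble `cell`, `subpop`.
#' @param groups the two subpopulations to compare (default: first two).
#' @param alpha_fdr FDR threshold (default 0.05).
#' @return Tibble `gene_id`, `median_a`, `median_b`, `p`, `q`, `direction`
#'   (`"up"`/`"down"` for significant genes, NA otherwise), all genes kept.
#' @export
differential_expression <- function(expr, labels, groups = NULL,
                                    alpha_fdr = 0.05) {
  check_columns(expr, c("gene_id", "cell", "fpkm"), "expr")
  check_columns(labels, c("cell", "subpop"), "labels")
  groups <- groups %||% sort(unique(labels$subpop))[1:2]
  dat <- dplyr::inner_join(expr, labels, by = "cell")
  dat <- dplyr::filter(dat, .data$subpop %in% groups)
  if (min(table(unique(dat[, c("cell", "subpop")])$subpop)) < 2) {
    stop_trio("need at least 2 cells per subpopulation")
  }
  dat <- dplyr::mutate(dat, y = log2(.data$fpkm + 1))
  res <- dat |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      median_a = median(.data$y[.data$subpop == groups[1]]),
      median_b = median(.data$y[.data$subpop == groups[2]]),
      p = if (length(unique(.data$y)) == 1L) 1 else {
        suppressWarnings(wilcox.test(.data$y[.data$subpop == groups[1]],
                                     .data$y[.data$subpop == groups[2]],
                                     exact = FALSE)$p.value)
      },
      .groups = "drop")
  res <- dplyr::mutate(res, q = p.adjust(.data$p, method = "BH"))
  dplyr::mutate(res,
                direction = dplyr::case_when(
                  .data$q < alpha_fdr & .data$median_a > .data$median_b ~ "up",
                  .data$q < alpha_fdr & .data$median_a < .data$median_b ~ "down",
                  TRUE ~ NA_character_))
}

#' Principal component analysis of cells from expression
#'
#' PCA on `log2(FPKM + 1)` with genes as features and cells as observations;
#' gene-wise centering, no unit-variance scaling (values are already on the
#' log scale). Component signs follow a deterministic convention: the
#' largest-magnitude gene loading of each component is positive.
#'
#' @param expr long tibble `gene_id`, `cell`, `fpkm`.
#' @param n_components components to retain (default 5, capped by the data).
#' @return An object of class `trio_pca` wrapping the `prcomp` fit, with
#'   `coords` (tibble `cell`, `PC1`, ...) and `var_explained`.
#' @export
pca_cells <- function(expr, n_components = 5) {
  check_columns(expr, c("gene_id", "cell", "fpkm"), "expr")
  wide <- expr |>
    dplyr::mutate(y = log2(.data$fpkm + 1)) |>
    dplyr::select("cell", "gene_id", "y") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "y")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$cell
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$rotation))
  for (j in seq_len(ncol(fit$rotation))) {
    i_max <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i_max, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  coords <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE]) |>
    dplyr::mutate(cell = rownames(fit$x), .before = 1)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(fit = fit, coords = coords,
                 var_explained = ve[seq_len(k)]),
            class = "trio_pca")
}

#' @export
print.trio_pca <- function(x, ...) {
  cat("<trio_pca> ", nrow(x$coords), " cells; variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

per_cell_bin_cor <- function(states, other, value_col, min_bins = 3) {
  joined <- dplyr::inner_join(states, other, by = c("cell", "bin_id"))
  out <- joined |>
    dplyr::filter(!is.na(.data$state), is.finite(.data[[value_col]])) |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      n_bins = dplyr::n(),
      r = if (dplyr::n() >= min_bins && sd(.data$state) > 0 &&
              sd(.data[[value_col]]) > 0) {
        cor(.data$state, .data[[value_col]])
      } else NA_real_,
      .groups = "drop")
  if (any(is.na(out$r))) {
    warn("correlation undefined for some cells (too few bins or zero variance)")
  }
  out
}

#' Per-cell correlation of integer copy number with window expression
#'
#' Pearson correlation, within each cell, between fitted integer copy states
#' and the relative expression value of the same genomic windows. A positive
#' correlation reflects the dosage effect of copy-number changes.
#'
#' @param profile tibble `cell`, `bin_id`, `state` (e.g.
#'   `tidy(fit)` of a [fit_cnv_hmm()] object).
#' @param window_expr tibble `cell`, `bin_id`, `value` from [expression_cnv()]
#'   or [window_cnv()].
#' @param min_bins minimum bins with both values (default 3).
#' @return Tibble `cell`, `n_bins`, `r`.
#' @export
copy_expression_cor <- function(profile, window_expr, min_bins = 3) {
  check_columns(profile, c("cell", "bin_id", "state"), "profile")
  check_columns(window_expr, c("cell", "bin_id", "value"), "window_expr")
  per_cell_bin_cor(profile, window_expr, "value", min_bins)
}

#' Per-cell correlation of integer copy number with window methylation
#'
#' Same contract as [copy_expression_cor()] with per-window mean methylation;
#' near-zero values indicate that copy-number changes do not shift methylation
#' levels.
#'
#' @param profile tibble `cell`, `bin_id`, `state`.
#' @param window_meth tibble `cell`, `bin_id`, `value` (mean methylation per
#'   window, e.g. from [window_methylation()]).
#' @param min_bins minimum bins with both values.
#' @return Tibble `cell`, `n_bins`, `r`.
#' @export
copy_methylation_cor <- function(profile, window_meth, min_bins = 3) {
  check_columns(profile, c("cell", "bin_id", "state"), "profile")
  check_columns(window_meth, c("cell", "bin_id", "value"), "window_meth")
  per_cell_bin_cor(profile, window_meth, "value", min_bins)
}

#' Mean methylation of copy-number bins per cell
#'
#' @param calls filtered calls with `cell`, `chrom`, `pos`, `level`.
#' @param bins tibble from [build_bins()].
#' @param min_cpgs minimum CpGs for a defined window value.
#' @return Tibble `cell`, `bin_id`, `value`, `n_cpgs`.
#' @export
window_methylation <- function(calls, bins, min_cpgs = 5) {
  check_columns(calls, c("cell", "chrom", "pos", "level"), "calls")
  regions <- tibble::tibble(window_id = bins$bin_id, chrom = bins$chrom,
                            start = bins$start, end = bins$end)
  hits <- calls_in_regions(calls, regions, "window_id")
  hits |>
    dplyr::group_by(.data$cell, bin_id = .data$region_id) |>
    dplyr::summarise(value = mean(.data$level), n_cpgs = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$n_cpgs >= min_cpgs)
}
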