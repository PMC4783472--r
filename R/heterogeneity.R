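#' Tile the genome into sliding-variance windows
#'
#' @param sizes chromosome sizes tibble (`chrom`, `size`) or named vector.
#' @param window window width in bp (default 3000).
#' @return Tibble `window_id`, `chrom`, `start`, `end`.
#' @export
tile_windows <- function(sizes, window = 3000) {
  b <- build_bins(sizes, window)
  tibble::tibble(window_id = b$bin_id, chrom = b$chrom, start = b$start,
                 end = b$end)
}

#' Per-window per-cell methylation mean and SEM
#'
#' The mean methylation rate of each window in each cell, with the standard
#' error of that mean taken over the window's detected CpG levels
#' (population-SD / sqrt(n)). When all levels agree the SD is zero, so the SEM
#' is floored at `sem_floor` to keep reciprocal weights finite.
#'
#' @param calls filtered calls with `cell`, `chrom`, `pos`, `level`.
#' @param windows tibble from [tile_windows()] (or any `window_id`, `chrom`,
#'   `start`, `end` table).
#' @param min_cpgs minimum detected CpGs per window per cell.
#' @param sem_floor lower bound for the SEM (default 0.01).
#' @return Tibble `window_id`, `cell`, `n_cpgs`, `mean`, `sem`.
#' @export
window_cell_stats <- function(calls, windows, min_cpgs = 5,
                              sem_floor = 0.01) {
  check_columns(calls, c("cell", "chrom", "pos", "level"), "calls")
  check_columns(windows, c("window_id", "chrom", "start", "end"), "windows")
  hits <- calls_in_regions(calls, windows, "window_id")
  if (nrow(hits) == 0L) {
    return(tibble::tibble(window_id = character(), cell = character(),
                          n_cpgs = integer(), mean = numeric(),
                          sem = numeric()))
  }
  hits |>
    dplyr::group_by(window_id = .data$region_id, .data$cell) |>
    dplyr::summarise(
      n_cpgs = dplyr::n(),
      mean = mean(.data$level),
      sem = pmax(sqrt(mean((.data$level - mean(.data$level))^2)) /
                   sqrt(dplyr::n()), sem_floor),
      .groups = "drop") |>
    dplyr::filter(.data$n_cpgs >= min_cpgs)
}

#' Reliability-weighted variance across cells
#'
#' Weighted variance of per-cell means with the unbiased reliability-weight
#' normalization: with weighted mean m = sum(w*x)/sum(w),
#' `V = sum(w * (x - m)^2) / (sum(w) - sum(w^2)/sum(w))`. With equal weights
#' this reduces to the ordinary sample variance.
#'
#' @param means numeric vector of per-cell window means (>= 2 values).
#' @param weights positive weights (reciprocal SEMs in the variance ranking).
#' @return The weighted variance (NA with < 2 cells).
#' @export
weighted_variance <- function(means, weights = rep(1, length(means))) {
  if (length(means) != length(weights)) {
    stop_trio("means and weights must have equal length")
  }
  if (any(weights <= 0)) stop_trio("weights must be positive")
  if (length(means) < 2L) return(NA_real_)
  sw <- sum(weights)
  m <- sum(weights * means) / sw
  sum(weights * (means - m)^2) / (sw - sum(weights^2) / sw)
}

#' Lower chi-squared confidence bound of a variance estimate
#'
#' `(n - 1) * V / qchisq((1 + confidence) / 2, n - 1)`: the lower end of the
#' classical chi-squared interval for a variance estimated from `n` cells.
#' Ranking windows by this bound (rather than by V itself) penalizes windows
#' observed in few cells.
#'
#' @param v variance estimate(s).
#' @param n_cells number of cells the estimate is based on.
#' @param confidence confidence level (default 0.95).
#' @return Lower bound(s), always <= `v`.
#' @export
variance_ci_lower <- function(v, n_cells, confidence = 0.95) {
  if (any(n_cells < 2)) stop_trio("n_cells must be >= 2")
  (n_cells - 1) * v / qchisq((1 + confidence) / 2, df = n_cells - 1)
}

#' Cell-to-cell methylation variance of genomic windows
#'
#' Combines [window_cell_stats()], [weighted_variance()] (weights = 1/SEM) and
#' [variance_ci_lower()] into one record per window with enough cells.
#'
#' @param stats output of [window_cell_stats()].
#' @param min_cells minimum cells with data per window (default 3).
#' @param confidence confidence level of the lower bound.
#' @return Tibble `window_id`, `n_cells`, `variance`, `ci_lower`.
#' @export
window_variance <- function(stats, min_cells = 3, confidence = 0.95) {
  check_columns(stats, c("window_id", "cell", "mean", "sem"), "stats")
  out <- stats |>
    dplyr::group_by(.data$window_id) |>
    dplyr::filter(dplyr::n() >= max(min_cells, 2L)) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      variance = weighted_variance(.data$mean, 1 / .data$sem),
      .groups = "drop")
  dplyr::mutate(out, ci_lower = variance_ci_lower(.data$variance,
                                                  .data$n_cells, confidence))
}

#' Rank windows by methylation heterogeneity
#'
#' Descending order of the variance lower bound, ties broken by genomic
#' coordinates so the ranking is deterministic and permutation-invariant.
#'
#' @param records output of [window_variance()].
#' @param windows the window coordinate table (for tie-breaks and output).
#' @param top_n how many windows to return (default 300); all if fewer exist.
#' @return The top `top_n` rows with coordinates and `rank` added.
#' @export
rank_variable_windows <- function(records, windows, top_n = 300) {
  check_columns(records, c("window_id", "ci_lower"), "records")
  out <- dplyr::inner_join(records,
                           windows[, c("window_id", "chrom", "start", "end")],
                           by = "window_id")
  out <- dplyr::arrange(out, dplyr::desc(.data$ci_lower), .data$chrom,
                        .data$start)
  out <- dplyr::mutate(out, rank = dplyr::row_number())
  head(out, top_n)
}

overlaps_any <- function(windows, elements) {
  hit <- rep(FALSE, nrow(windows))
  for (chr in unique(windows$chrom)) {
    wi <- which(windows$chrom == chr)
    el <- elements[elements$chrom == chr, ]
    if (nrow(el) == 0L) next
    ov <- IRanges::countOverlaps(
      IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi]),
      IRanges::IRanges(el$start + 1L, el$end))
    hit[wi] <- ov > 0
  }
  hit
}

#' Genomic-element enrichment of the top variable windows
#'
#' For each element class (CGIs, promoters, ...), builds the 2x2 table of
#' (window in top set) x (window overlaps element, >= 1 bp) over all scored
#' windows, tests it with a two-sided Fisher's exact test, and adjusts across
#' element classes with Benjamini-Hochberg.
#'
#' @param top_windows output of [rank_variable_windows()].
#' @param all_windows every scored window (same columns).
#' @param elements named list of interval tibbles (`chrom`, `start`, `end`).
#' @return Tibble `element`, `n_top_in`, `n_bg_in`, `odds_ratio`, `p`, `fdr`.
#' @export
element_enrichment <- function(top_windows, all_windows, elements) {
  if (is.null(names(elements))) stop_trio("elements must be a named list")
  bg <- dplyr::anti_join(all_windows, top_windows[, "window_id"],
                         by = "window_id")
  purrr::imap_dfr(elements, function(el, name) {
    top_in <- overlaps_any(top_windows, el)
    bg_in <- overlaps_any(bg, el)
    tab <- matrix(c(sum(top_in), sum(!top_in), sum(bg_in), sum(!bg_in)),
                  nrow = 2)
    ft <- fisher.test(tab)
    tibble::tibble(element = name, n_top_in = sum(top_in),
                   n_bg_in = sum(bg_in),
                   odds_ratio = unname(ft$estimate), p = ft$p.value)
  }) |>
    dplyr::mutate(fdr = p.adjust(.data$p, method = "BH"))
}
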