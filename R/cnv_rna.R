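#' Select expressed genes for expression-based CNV inference
#'
#' Keeps genes whose mean `log2(FPKM + 1)` across all single cells exceeds the
#' threshold; lowly expressed genes carry no dosage signal and only add noise
#' to the moving average.
#'
#' @param expr long tibble `gene_id`, `cell`, `fpkm`.
#' @param threshold minimum mean log2(FPKM + 1) (default 1.5).
#' @return `expr` restricted to the selected genes.
#' @export
select_expressed_genes <- function(expr, threshold = 1.5) {
  check_columns(expr, c("gene_id", "cell", "fpkm"), "expr")
  keep <- expr |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(m = mean(log2(.data$fpkm + 1)), .groups = "drop") |>
    dplyr::filter(.data$m > threshold)
  dplyr::filter(expr, .data$gene_id %in% keep$gene_id)
}

#' Reference-relative expression
#'
#' Normalizes single-cell expression to a bulk diploid reference:
#' `log2(FPKM_cell + 1) - log2(FPKM_ref + 1)` per gene and cell.
#'
#' @param expr long tibble `gene_id`, `cell`, `fpkm`.
#' @param reference tibble `gene_id`, `fpkm` of the normal reference.
#' @return Tibble `gene_id`, `cell`, `value`.
#' @export
relative_expression <- function(expr, reference) {
  check_columns(expr, c("gene_id", "cell", "fpkm"), "expr")
  check_columns(reference, c("gene_id", "fpkm"), "reference")
  missing <- setdiff(unique(expr$gene_id), reference$gene_id)
  if (length(missing) > 0L) {
    stop_trio("gene(s) missing from reference: ",
              paste(head(missing, 3), collapse = ", "))
  }
  out <- dplyr::inner_join(expr,
                           dplyr::rename(reference, ref_fpkm = "fpkm"),
                           by = "gene_id")
  out <- dplyr::mutate(out, value = log2(.data$fpkm + 1) -
                         log2(.data$ref_fpkm + 1))
  dplyr::select(out, "gene_id", "cell", "value")
}

# Moving-window mean excluding the focal element, truncated at the ends.
window_mean_excl_self <- function(x, half_window) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_window)
  hi <- pmin(n, i + half_window)
  (cs[hi + 1L] - cs[lo] - x) / (hi - lo)
}

#' Moving-average copy-number estimate from ordered gene expression
#'
#' For each gene, the CNV value is the mean expression value of the
#' `2 * half_window` genes around it on the same chromosome (up to
#' `half_window` upstream and downstream neighbours in genomic order), the
#' focal gene excluded; windows truncate at chromosome ends. The values are
#' normally reference-relative log values (see [expression_cnv()] for the raw
#' FPKM mode).
#'
#' @param values tibble `gene_id`, `cell`, `value`.
#' @param genes gene annotation tibble `gene_id`, `chrom`, `tss`.
#' @param half_window neighbours on each side (default 50, a 100-gene window).
#' @return Tibble `gene_id`, `cell`, `chrom`, `tss`, `cnv`.
#' @export
moving_average_cnv <- function(values, genes, half_window = 50) {
  check_columns(values, c("gene_id", "cell", "value"), "values")
  check_columns(genes, c("gene_id", "chrom", "tss"), "genes")
  out <- dplyr::inner_join(values, genes[, c("gene_id", "chrom", "tss")],
                           by = "gene_id")
  out |>
    dplyr::group_by(.data$cell, .data$chrom) |>
    dplyr::arrange(.data$tss, .by_group = TRUE) |>
    dplyr::mutate(cnv = window_mean_excl_self(.data$value, half_window)) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "cell", "chrom", "tss", "cnv") |>
    dplyr::arrange(.data$cell, .data$chrom, .data$tss)
}

#' Center per-gene CNV values within each cell
#'
#' Subtracts each cell's mean CNV value so that profiles are comparable
#' across cells regardless of per-cell offsets; the post-centering mean is 0.
#'
#' @param cnv tibble with `cell` and `cnv` columns (NA values ignored).
#' @return The same tibble with `cnv` centered per cell.
#' @export
center_cnv <- function(cnv) {
  check_columns(cnv, c("cell", "cnv"), "cnv")
  cnv |>
    dplyr::group_by(.data$cell) |>
    dplyr::mutate(cnv = .data$cnv - mean(.data$cnv, na.rm = TRUE)) |>
    dplyr::ungroup()
}

#' Aggregate gene-level CNV values into genomic windows
#'
#' The relative CNV value of a window is the mean over the selected genes
#' whose TSS lies in it; windows containing no selected gene are undefined
#' (absent from the output).
#'
#' @param cnv tibble `gene_id`, `cell`, `cnv` (with `chrom`, `tss` columns or
#'   joined via `genes`).
#' @param genes gene annotation `gene_id`, `chrom`, `tss`.
#' @param bins tibble from [build_bins()].
#' @return Tibble `cell`, `bin_id`, `value`, `n_genes`.
#' @export
window_cnv <- function(cnv, genes, bins) {
  check_columns(cnv, c("gene_id", "cell", "cnv"), "cnv")
  g <- genes[, c("gene_id", "chrom", "tss")]
  g$bin_id <- assign_to_bins(g$chrom, g$tss, bins, "gene")
  out <- dplyr::inner_join(cnv[, c("gene_id", "cell", "cnv")],
                           g[, c("gene_id", "bin_id")], by = "gene_id")
  out |>
    dplyr::filter(is.finite(.data$cnv)) |>
    dplyr::group_by(.data$cell, .data$bin_id) |>
    dplyr::summarise(value = mean(.data$cnv), n_genes = dplyr::n(),
                     .groups = "drop")
}

#' Expression-based relative CNV pipeline
#'
#' Runs the full chain select -> reference-relative -> 100-gene moving
#' average -> per-cell centering -> window aggregation, returning the window
#' matrix ready for clustering or correlation with integer copy numbers.
#'
#' @inheritParams select_expressed_genes
#' @inheritParams relative_expression
#' @inheritParams moving_average_cnv
#' @param bins tibble from [build_bins()].
#' @return Tibble `cell`, `bin_id`, `value`, `n_genes`.
#' @export
expression_cnv <- function(expr, reference, genes, bins, threshold = 1.5,
                           half_window = 50, mode = c("relative", "fpkm")) {
  mode <- match.arg(mode)
  sel <- select_expressed_genes(expr, threshold)
  vals <- if (mode == "relative") {
    relative_expression(sel, reference)
  } else {
    dplyr::rename(sel, value = "fpkm")
  }
  ma <- moving_average_cnv(vals, genes, half_window)
  ma <- center_cnv(ma)
  window_cnv(ma, genes, bins)
}
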