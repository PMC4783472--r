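#' Plot a copy-number profile
#'
#' Normalized copy values (points) and fitted integer states (step segments)
#' along the genome for one or more cells, faceted by cell.
#'
#' @param fit a `trio_cnv` object.
#' @param cells cells to show (default: all).
#' @return A ggplot object.
#' @export
plot_cnv_profile <- function(fit, cells = NULL) {
  stopifnot(inherits(fit, "trio_cnv"))
  prof <- dplyr::filter(fit$profile, !.data$masked)
  if (!is.null(cells)) prof <- dplyr::filter(prof, .data$cell %in% cells)
  prof <- dplyr::mutate(prof, mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.8,
                        alpha = 0.7, colour = "grey40") +
    ggplot2::geom_step(ggplot2::aes(y = .data$state), colour = "firebrick",
                       linewidth = 0.7) +
    ggplot2::facet_grid(cell ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "copy number") +
    ggplot2::theme_bw()
}

#' @exportS3Method ggplot2::autoplot
autoplot.trio_cnv <- function(object, ...) plot_cnv_profile(object, ...)

#' Plot a metagene methylation profile
#'
#' The 30-fraction profile across the upstream flank, gene body and
#' downstream flank, showing the TSS hypomethylation valley.
#'
#' @param profile tibble from [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  check_columns(profile, c("fraction", "zone", "level"), "profile")
  n_flank <- sum(profile$zone == "upstream")
  n_body <- sum(profile$zone == "body")
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$fraction,
                                        y = .data$level)) +
    ggplot2::geom_vline(xintercept = c(n_flank + 0.5, n_flank + n_body + 0.5),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.2, colour = "steelblue") +
    ggplot2::scale_x_continuous(
      breaks = c(1, n_flank + 0.5, n_flank + n_body + 0.5,
                 n_flank * 2 + n_body),
      labels = c("-flank", "TSS", "TES", "+flank")) +
    ggplot2::labs(x = NULL, y = "mean methylation level") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Plot the per-fraction methylation-expression correlation curve
#'
#' @param curve tibble from [fraction_expression_cor()].
#' @return A ggplot object.
#' @export
plot_fraction_cor <- function(curve) {
  check_columns(curve, c("fraction", "zone", "r"), "curve")
  n_flank <- sum(curve$zone == "upstream")
  n_body <- sum(curve$zone == "body")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fraction, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = c(n_flank + 0.5, n_flank + n_body + 0.5),
                        linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::geom_point(size = 1.2, colour = "darkorange") +
    ggplot2::labs(x = "metagene fraction",
                  y = "methylation-expression Pearson r") +
    ggplot2::theme_bw()
}

#' Plot cells on the first two principal components
#'
#' @param pca a `trio_pca` object.
#' @param labels optional tibble `cell`, `subpop` to colour by.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, labels = NULL) {
  stopifnot(inherits(pca, "trio_pca"))
  coords <- pca$coords
  if (!is.null(labels)) {
    coords <- dplyr::inner_join(coords, labels, by = "cell")
  }
  p <- ggplot2::ggplot(coords, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$var_explained[2])) +
    ggplot2::theme_bw()
  if (is.null(labels)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$subpop), size = 2)
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.trio_pca <- function(object, ...) plot_pca(object, ...)
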