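#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted copy-number object
#'
#' @param x a `trio_cnv` object from [fit_cnv_hmm()].
#' @param ... unused.
#' @return The per-cell per-bin profile tibble (`cell`, `bin_id`, `chrom`,
#'   `start`, `end`, `value`, `state`, `masked`).
#' @exportS3Method generics::tidy
tidy.trio_cnv <- function(x, ...) x$profile

#' @rdname tidy.trio_cnv
#' @exportS3Method generics::glance
glance.trio_cnv <- function(x, ...) {
  segs <- cnv_segments(x)
  tibble::tibble(n_cells = length(unique(x$profile$cell)),
                 n_bins = length(unique(x$profile$bin_id)),
                 n_masked = sum(x$profile$masked) /
                   max(length(unique(x$profile$cell)), 1L),
                 n_segments = nrow(segs),
                 sigma = x$sigma, stay_prob = x$stay_prob)
}

#' Tidy a cell clustering
#'
#' @param x a `trio_clustering` object from [cluster_cells()].
#' @param ... unused.
#' @return Tibble `cell`, `cluster`.
#' @exportS3Method generics::tidy
tidy.trio_clustering <- function(x, ...) x$labels

#' @rdname tidy.trio_clustering
#' @exportS3Method generics::glance
glance.trio_clustering <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$labels), k = x$k,
                 linkage = x$tree$method)
}

#' Tidy a cell PCA
#'
#' @param x a `trio_pca` object from [pca_cells()].
#' @param ... unused.
#' @return Tibble of cell coordinates on the retained components.
#' @exportS3Method generics::tidy
tidy.trio_pca <- function(x, ...) x$coords

#' @rdname tidy.trio_pca
#' @exportS3Method generics::glance
glance.trio_pca <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$coords),
                 n_components = length(x$var_explained),
                 var_explained_pc1 = x$var_explained[1],
                 var_explained_total = sum(x$var_explained))
}
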