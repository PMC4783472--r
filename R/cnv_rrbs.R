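#' Per-bin sequenced-base depth from aligned read intervals
#'
#' Sums, for every bin, the overlap length of each read with the bin
#' (equivalent to summing per-position depth over the bin). Reads straddling a
#' bin boundary contribute to each bin proportionally to the overlap.
#'
#' @param reads tibble with `chrom`, `start`, `end` (0-based half-open) and an
#'   optional `cell` column.
#' @param bins tibble from [build_bins()].
#' @return A tibble `cell` (if present), `bin_id`, `depth`, one row per
#'   cell-bin with nonzero overlap plus zero rows for empty bins.
#' @export
bin_depth <- function(reads, bins) {
  check_columns(reads, c("chrom", "start", "end"), "reads")
  has_cell <- "cell" %in% names(reads)
  if (!has_cell) reads$cell <- "sample"
  bad_chrom <- setdiff(unique(reads$chrom), unique(bins$chrom))
  if (length(bad_chrom) > 0L) {
    stop_trio("read interval on unknown chromosome: ", bad_chrom[1])
  }
  pieces <- purrr::map_dfr(unique(reads$chrom), function(chr) {
    r <- reads[reads$chrom == chr, ]
    b <- bins[bins$chrom == chr, ]
    b <- b[order(b$start), ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(r$start + 1L, r$end),
      IRanges::IRanges(b$start + 1L, b$end))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    tibble::tibble(cell = r$cell[qi], bin_id = b$bin_id[si],
                   ov = pmin(r$end[qi], b$end[si]) -
                     pmax(r$start[qi], b$start[si]))
  })
  depth <- dplyr::summarise(dplyr::group_by(pieces, .data$cell, .data$bin_id),
                            depth = sum(.data$ov), .groups = "drop")
  grid <- tidyr::expand_grid(cell = unique(reads$cell), bin_id = bins$bin_id)
  out <- dplyr::left_join(grid, depth, by = c("cell", "bin_id"))
  out <- dplyr::mutate(out, depth = tidyr::replace_na(.data$depth, 0))
  if (!has_cell) out$cell <- NULL
  out
}

#' Per-bin normalization factors from a diploid control
#'
#' RRBS coverage is highly non-uniform, so raw per-bin depth cannot be read as
#' copy number. The control profile (bulk RRBS of normal tissue) defines a
#' per-bin factor: its library-size-normalized depth, averaged across control
#' replicates when several are given. Bins with zero control depth are masked.
#'
#' @param control tibble with `bin_id`, `depth` and an optional `control_id`
#'   column for replicates.
#' @param bins tibble from [build_bins()]; its `masked` column is respected and
#'   extended.
#' @return `bins` with columns `factor` and updated `masked`.
#' @export
normalization_factors <- function(control, bins) {
  check_columns(control, c("bin_id", "depth"), "control")
  if (!"control_id" %in% names(control)) control$control_id <- "control"
  if (any(control$depth < 0)) stop_trio("control depths must be >= 0")
  unmasked <- bins$bin_id[!bins$masked]
  norm <- control |>
    dplyr::filter(.data$bin_id %in% unmasked) |>
    dplyr::group_by(.data$control_id) |>
    dplyr::mutate(rel = .data$depth / sum(.data$depth)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(factor = mean(.data$rel), .groups = "drop")
  if (all(norm$factor == 0)) stop_trio("control has zero library total")
  out <- dplyr::left_join(bins, norm, by = "bin_id")
  dplyr::mutate(out,
                factor = ifelse(.data$masked, NA_real_, .data$factor),
                masked = .data$masked | is.na(.data$factor) | .data$factor == 0)
}

#' Normalize per-bin depth to copy-number values
#'
#' Converts depth to a continuous copy value anchored at 2 for the diploid
#' control: `value = 2 * (depth / library_total) / factor`, with the library
#' total taken over unmasked bins. A cell whose depth is distributed like the
#' control therefore reads 2.0 in every bin, and scaling all of a cell's
#' depths by a constant changes nothing.
#'
#' @param depth tibble with `cell`, `bin_id`, `depth`.
#' @param factors output of [normalization_factors()].
#' @return Tibble `cell`, `bin_id`, `value`, `masked`.
#' @export
normalize_bins <- function(depth, factors) {
  check_columns(depth, c("cell", "bin_id", "depth"), "depth")
  check_columns(factors, c("bin_id", "factor", "masked"), "factors")
  if (all(factors$masked)) stop_trio("all bins are masked")
  out <- dplyr::inner_join(depth, factors[, c("bin_id", "factor", "masked")],
                           by = "bin_id")
  out <- out |>
    dplyr::group_by(.data$cell) |>
    dplyr::mutate(lib = sum(.data$depth[!.data$masked])) |>
    dplyr::ungroup()
  if (any(out$lib == 0)) {
    stop_trio("cell with zero depth on unmasked bins: ",
              out$cell[out$lib == 0][1])
  }
  out <- dplyr::mutate(out,
                       value = ifelse(.data$masked, NA_real_,
                                      2 * (.data$depth / .data$lib) / .data$factor))
  dplyr::select(out, "cell", "bin_id", "value", "masked")
}

# Viterbi decoding of one value sequence; emissions N(state, sigma), uniform
# initial distribution, stay/switch transitions. Ties broken toward the state
# closest to copy 2 (then the smaller state).
viterbi_integer <- function(x, states, sigma, stay_prob) {
  k <- length(states)
  n <- length(x)
  pref <- order(abs(states - 2), states)  # tie-break preference order
  pick <- function(score) pref[which.max(score[pref])]
  emis <- vapply(states, function(s) dnorm(x, s, sigma, log = TRUE),
                 numeric(n))
  emis <- matrix(emis, nrow = n)
  if (k == 1L) return(rep(states, n))
  lstay <- log(stay_prob)
  lswitch <- log((1 - stay_prob) / (k - 1))
  delta <- -log(k) + emis[1, ]
  back <- matrix(NA_integer_, nrow = n, ncol = k)
  if (n > 1) {
    for (t in 2:n) {
      new <- numeric(k)
      for (j in seq_len(k)) {
        cand <- delta + ifelse(seq_len(k) == j, lstay, lswitch)
        b <- pick(cand)
        back[t, j] <- b
        new[j] <- cand[b] + emis[t, j]
      }
      delta <- new
    }
  }
  path <- integer(n)
  path[n] <- pick(delta)
  if (n > 1) for (t in n:2) path[t - 1] <- back[t, path[t]]
  states[path]
}

#' Fit integer copy-number states with a hidden Markov model
#'
#' Decodes each cell's normalized copy values into integer states by Viterbi
#' decoding, one chain per chromosome (no transitions across chromosome
#' boundaries). Emissions are Gaussian with mean equal to the integer copy
#' number on the diploid = 2 scale and a shared standard deviation; the chain
#' stays in its state with probability `stay_prob` and otherwise switches
#' uniformly. Masked bins carry no state.
#'
#' @param values tibble `cell`, `bin_id`, `value`, `masked` from
#'   [normalize_bins()].
#' @param bins tibble from [build_bins()] (for chromosome order).
#' @param states integer states to consider.
#' @param sigma emission standard deviation (> 0).
#' @param stay_prob self-transition probability.
#' @return An object of class `trio_cnv` with element `profile`: tibble
#'   `cell`, `bin_id`, `chrom`, `start`, `end`, `value`, `state`, `masked`.
#' @export
fit_cnv_hmm <- function(values, bins, states = 0:6, sigma = 0.4,
                        stay_prob = 1 - 1e-4) {
  check_number(sigma, "sigma", min = 0, strict = TRUE)
  if (stay_prob <= 0 || stay_prob >= 1) {
    stop_trio("stay_prob must lie in (0, 1)")
  }
  check_columns(values, c("cell", "bin_id", "value"), "values")
  if (!"masked" %in% names(values)) values$masked <- FALSE
  prof <- dplyr::inner_join(values,
                            bins[, c("bin_id", "chrom", "start", "end")],
                            by = "bin_id")
  prof <- dplyr::arrange(prof, .data$cell, .data$chrom, .data$start)
  prof$state <- NA_integer_
  idx <- split(seq_len(nrow(prof)),
               list(prof$cell, prof$chrom), drop = TRUE)
  for (ii in idx) {
    use <- ii[!prof$masked[ii] & is.finite(prof$value[ii])]
    if (length(use) == 0L) next
    prof$state[use] <- viterbi_integer(prof$value[use], states, sigma,
                                       stay_prob)
  }
  structure(list(profile = tibble::as_tibble(
    prof[, c("cell", "bin_id", "chrom", "start", "end", "value", "state",
             "masked")]),
    states = states, sigma = sigma, stay_prob = stay_prob),
    class = "trio_cnv")
}

#' @export
print.trio_cnv <- function(x, ...) {
  cat("<trio_cnv> ", length(unique(x$profile$cell)), " cell(s) x ",
      length(unique(x$profile$bin_id)), " bins; states ",
      paste(range(x$states), collapse = ".."), ", sigma ", x$sigma, "\n",
      sep = "")
  invisible(x)
}

#' Constant-state segments of a fitted profile
#'
#' @param fit a `trio_cnv` object.
#' @return Tibble `cell`, `chrom`, `start`, `end`, `state`, `n_bins` with one
#'   row per maximal run of identical states over unmasked bins.
#' @export
cnv_segments <- function(fit) {
  stopifnot(inherits(fit, "trio_cnv"))
  prof <- dplyr::filter(fit$profile, !.data$masked, !is.na(.data$state))
  prof |>
    dplyr::group_by(.data$cell, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$state) != 0L))) |>
    dplyr::group_by(.data$cell, .data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     state = .data$state[1], n_bins = dplyr::n(),
                     .groups = "drop") |>
    dplyr::select(-"run") |>
    dplyr::arrange(.data$cell, .data$chrom, .data$start)
}

#' Sensitivity and specificity of copy-number deduction
#'
#' Scores normalized copy values against known truth. Specificity is the
#' fraction of truth-diploid bins whose value falls inside (1.5, 2.5);
#' sensitivity is the fraction of truth-aberrant bins whose value lies within
#' `window_tol` of the true copy (e.g. (0.5, 1.5) for a single-copy X).
#'
#' @param values tibble `cell`, `bin_id`, `value` (masked rows ignored).
#' @param truth tibble `cell`, `bin_id`, `copy`, or `bin_id`, `copy` applied
#'   to every cell.
#' @param window_tol half-width of the acceptance window around the true copy.
#' @return One-row tibble with `sensitivity`, `specificity`, and bin counts.
#' @export
cnv_sensitivity_specificity <- function(values, truth, window_tol = 0.5) {
  check_columns(values, c("cell", "bin_id", "value"), "values")
  check_columns(truth, c("bin_id", "copy"), "truth")
  if ("masked" %in% names(values)) {
    values <- dplyr::filter(values, !.data$masked)
  }
  values <- dplyr::filter(values, is.finite(.data$value))
  joined <- if ("cell" %in% names(truth)) {
    dplyr::inner_join(values, truth, by = c("cell", "bin_id"))
  } else {
    dplyr::inner_join(values, truth, by = "bin_id")
  }
  dip <- joined$copy == 2
  ab <- !dip
  hit <- abs(joined$value - joined$copy) < window_tol
  tibble::tibble(
    sensitivity = if (any(ab)) mean(hit[ab]) else NA_real_,
    specificity = if (any(dip)) mean(hit[dip]) else NA_real_,
    n_diploid_bins = sum(dip), n_aberrant_bins = sum(ab))
}

#' Hierarchical clustering of cells from per-bin values
#'
#' Average-linkage hierarchical clustering on Euclidean distance across
#' unmasked bins, cut into `k` clusters. Bins undefined in some cells are
#' dropped pairwise by the distance computation.
#'
#' @param values tibble `cell`, `bin_id` (or any feature id column named by
#'   `feature`), `value`.
#' @param k number of clusters to cut.
#' @param linkage agglomeration method (default `"average"`).
#' @param feature name of the feature column.
#' @return An object of class `trio_clustering` with `labels` (tibble `cell`,
#'   `cluster`), the `hclust` tree, and `k`.
#' @export
cluster_cells <- function(values, k = 2, linkage = "average",
                          feature = "bin_id") {
  check_columns(values, c("cell", feature, "value"), "values")
  if ("masked" %in% names(values)) {
    values <- dplyr::filter(values, !.data$masked)
  }
  wide <- tidyr::pivot_wider(values[, c("cell", feature, "value")],
                             names_from = dplyr::all_of(feature),
                             values_from = "value")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$cell
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (nrow(mat) < 2L) stop_trio("need at least 2 cells to cluster")
  d <- dist(mat)
  if (any(!is.finite(d))) {
    stop_trio("cells with no shared defined features cannot be clustered")
  }
  if (all(d == 0)) {
    # identical cells: one flat cluster, deterministic labeling
    labels <- tibble::tibble(cell = rownames(mat), cluster = 1L)
    tree <- hclust(d, method = linkage)
    return(structure(list(labels = labels, tree = tree, k = 1L),
                     class = "trio_clustering"))
  }
  tree <- hclust(d, method = linkage)
  cl <- cutree(tree, k = k)
  structure(list(labels = tibble::tibble(cell = names(cl),
                                         cluster = as.integer(cl)),
                 tree = tree, k = as.integer(k)),
            class = "trio_clustering")
}

#' @export
print.trio_clustering <- function(x, ...) {
  cat("<trio_clustering> ", nrow(x$labels), " cells in ", x$k,
      " cluster(s): ", paste(table(x$labels$cluster), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}

#' Mask bins with unreliable RRBS coverage
#'
#' Bins whose unique-fragment count falls below a fraction of the genome-wide
#' median are masked (a data-driven stand-in for excluding centromeric and
#' telomeric windows) and excluded from all downstream statistics.
#'
#' @param bins_with_counts output of [count_fragments_per_bin()].
#' @param min_frac mask threshold as a fraction of the median count.
#' @return The bins tibble with `masked` updated.
#' @export
mask_low_coverage_bins <- function(bins_with_counts, min_frac = 0.1) {
  check_columns(bins_with_counts, "n_fragments", "bins_with_counts")
  med <- median(bins_with_counts$n_fragments)
  dplyr::mutate(bins_with_counts,
                masked = .data$masked |
                  .data$n_fragments < min_frac * med)
}

#' Refine copy-number segments over highly covered fine bins
#'
#' RRBS coverage is concentrated in CpG-rich regions, so resolution can be
#' raised by re-running normalization and HMM fitting on finer bins restricted
#' to those with adequate unique-fragment support. Bins below `min_fragments`
#' are masked; segment boundaries are reported at the fine-bin scale.
#'
#' @param depth tibble `cell`, `bin_id`, `depth` at the fine bin scale.
#' @param control control depth at the same scale.
#' @param fine_bins fine-scale [build_bins()] tibble with `n_fragments`
#'   (from [count_fragments_per_bin()]).
#' @param min_fragments minimum unique fragments for a fine bin to be used.
#' @param ... passed to [fit_cnv_hmm()].
#' @return List with the `trio_cnv` fit and a `segments` tibble.
#' @export
refine_cnv_segments <- function(depth, control, fine_bins, min_fragments = 20,
                                ...) {
  check_columns(fine_bins, "n_fragments", "fine_bins")
  fine_bins <- dplyr::mutate(fine_bins,
                             masked = .data$masked |
                               .data$n_fragments < min_fragments)
  if (all(fine_bins$masked)) {
    warn("no fine bin reaches the fragment threshold; nothing to refine")
    return(list(fit = NULL,
                segments = tibble::tibble(cell = character(),
                                          chrom = character(),
                                          start = integer(), end = integer(),
                                          state = integer(),
                                          n_bins = integer())))
  }
  factors <- normalization_factors(control, fine_bins)
  values <- normalize_bins(depth, factors)
  fit <- fit_cnv_hmm(values, fine_bins, ...)
  list(fit = fit, segments = cnv_segments(fit))
}
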