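test_that("bin depth sums read-bin overlap and conserves total bases", {
  bins <- build_bins(c(chr1 = 2e7), 1e7)
  reads <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  expect_equal(bin_depth(reads, bins)$depth, c(100, 0))

  straddle <- tibble::tibble(chrom = "chr1", start = 1e7 - 30, end = 1e7 + 70)
  expect_equal(bin_depth(straddle, bins)$depth, c(30, 70))

  set.seed(7)
  n <- 200
  rnd <- tibble::tibble(cell = sample(c("a", "b"), n, replace = TRUE),
                        chrom = "chr1",
                        start = sample(0:(2e7 - 150), n))
  rnd$end <- rnd$start + sample(50:150, n, replace = TRUE)
  out <- bin_depth(rnd, bins)
  expect_equal(sum(out$depth), sum(rnd$end - rnd$start))

  expect_error(bin_depth(tibble::tibble(chrom = "chrZ", start = 0, end = 10),
                         bins), "chrZ")
})

test_that("normalization factors are control-proportional and mask zeros", {
  bins <- build_bins(c(chr1 = 3e7), 1e7)
  ctrl <- tibble::tibble(bin_id = bins$bin_id, depth = c(100, 300, 0))
  f <- normalization_factors(ctrl, bins)
  expect_equal(f$factor[1:2], c(0.25, 0.75))
  expect_true(f$masked[3])

  # two identical controls equal one
  ctrl2 <- dplyr::bind_rows(dplyr::mutate(ctrl, control_id = "r1"),
                            dplyr::mutate(ctrl, control_id = "r2"))
  expect_equal(normalization_factors(ctrl2, bins)$factor, f$factor)
})

test_that("normalized copy values follow the diploid-anchored formula", {
  bins2 <- build_bins(c(chr1 = 2e7), 1e7)
  ctrl <- tibble::tibble(bin_id = bins2$bin_id, depth = c(1, 1))
  f <- normalization_factors(ctrl, bins2)

  # self-normalization identity
  same <- tibble::tibble(cell = "c", bin_id = bins2$bin_id, depth = c(5, 5))
  expect_equal(normalize_bins(same, f)$value, c(2, 2))

  # hand oracle: depths (2,1) vs flat control -> 2*(2/3)/(1/2) = 8/3
  cell <- tibble::tibble(cell = "c", bin_id = bins2$bin_id, depth = c(2, 1))
  expect_equal(normalize_bins(cell, f)$value, c(8 / 3, 4 / 3))

  # 3-bin hand oracle
  bins3 <- build_bins(c(chr1 = 3e7), 1e7)
  f3 <- normalization_factors(
    tibble::tibble(bin_id = bins3$bin_id, depth = c(1, 1, 1)), bins3)
  cell3 <- tibble::tibble(cell = "c", bin_id = bins3$bin_id,
                          depth = c(2, 1, 1))
  expect_equal(normalize_bins(cell3, f3)$value, c(3, 1.5, 1.5))

  # library-size invariance
  scaled <- dplyr::mutate(cell3, depth = depth * 17)
  expect_equal(normalize_bins(scaled, f3)$value,
               normalize_bins(cell3, f3)$value)

  all_masked <- dplyr::mutate(f3, masked = TRUE)
  expect_error(normalize_bins(cell3, all_masked), "masked")
})

test_that("increasing a bin's depth never decreases its normalized value", {
  bins <- build_bins(c(chr1 = 4e7), 1e7)
  f <- normalization_factors(
    tibble::tibble(bin_id = bins$bin_id, depth = c(2, 1, 3, 2)), bins)
  base <- tibble::tibble(cell = "c", bin_id = bins$bin_id,
                         depth = c(10, 20, 30, 40))
  v0 <- normalize_bins(base, f)$value[2]
  for (extra in c(1, 5, 50)) {
    up <- base
    up$depth[2] <- up$depth[2] + extra
    expect_gte(normalize_bins(up, f)$value[2], v0)
  }
})

test_that("Viterbi decoding matches direct expectations on clean signals", {
  bins <- build_bins(c(chr1 = 6e7), 1e7)
  vals <- tibble::tibble(cell = "c", bin_id = bins$bin_id,
                         value = rep(2, 6), masked = FALSE)
  fit <- fit_cnv_hmm(vals, bins)
  expect_equal(fit$profile$state, rep(2L, 6))

  # breakpoint sequence: the enumeration oracle fixes the expected path at
  # these exact parameters (a moderately sticky chain detects it)
  vals2 <- dplyr::mutate(vals, value = c(2, 2, 2, 3, 3, 3))
  exp_path <- oracle_viterbi(vals2$value, 0:6, sigma = 0.4, stay_prob = 0.9)
  expect_equal(exp_path, c(2, 2, 2, 3, 3, 3))
  fit2 <- fit_cnv_hmm(vals2, bins, stay_prob = 0.9)
  expect_equal(fit2$profile$state, exp_path)

  # with the very sticky default chain the same noiseless step is smoothed
  # away; the oracle agrees
  exp_sticky <- oracle_viterbi(vals2$value, 0:6, 0.4, 1 - 1e-4)
  fit3 <- fit_cnv_hmm(vals2, bins)
  expect_equal(fit3$profile$state, exp_sticky)

  expect_error(fit_cnv_hmm(vals, bins, sigma = 0), "sigma")
})

test_that("Viterbi equals exhaustive path enumeration on random instances", {
  set.seed(1234)
  states <- 0:4
  for (i in 1:60) {
    n <- sample(2:7, 1)
    sigma <- runif(1, 0.2, 0.6)
    stay <- runif(1, 0.5, 0.999)
    x <- runif(n, -0.5, 4.5)
    bins <- build_bins(c(chr1 = n * 1e7), 1e7)
    vals <- tibble::tibble(cell = "c", bin_id = bins$bin_id, value = x,
                           masked = FALSE)
    fit <- fit_cnv_hmm(vals, bins, states = states, sigma = sigma,
                       stay_prob = stay)
    expect_equal(fit$profile$state, oracle_viterbi(x, states, sigma, stay))
  }
})

test_that("HMM chains never cross chromosome boundaries", {
  bins <- build_bins(c(chr1 = 2e7, chr2 = 2e7), 1e7)
  # one aberrant bin per chromosome end: a single chain would smooth them
  vals <- tibble::tibble(cell = "c", bin_id = bins$bin_id,
                         value = c(3, 3, 1, 1), masked = FALSE)
  fit <- fit_cnv_hmm(vals, bins)
  expect_equal(fit$profile$state[fit$profile$chrom == "chr1"], c(3L, 3L))
  expect_equal(fit$profile$state[fit$profile$chrom == "chr2"], c(1L, 1L))
})

test_that("sensitivity and specificity follow the acceptance windows", {
  vals <- tibble::tibble(cell = "c", bin_id = paste0("b", 1:6),
                         value = c(2, 2, 2, 2, 1, 1))
  truth <- tibble::tibble(bin_id = paste0("b", 1:6),
                          copy = c(2, 2, 2, 2, 1, 1))
  ss <- cnv_sensitivity_specificity(vals, truth)
  expect_equal(ss$specificity, 1)
  expect_equal(ss$sensitivity, 1)

  # values at the window edge are outside the open interval
  edge <- dplyr::mutate(vals, value = c(2.5, 2, 2, 2, 1.5, 1))
  ss2 <- cnv_sensitivity_specificity(edge, truth)
  expect_equal(ss2$specificity, 0.75)
  expect_equal(ss2$sensitivity, 0.5)
})

test_that("Gaussian-noise specificity matches the normal-tail closed form", {
  set.seed(99)
  n <- 4000
  vals <- tibble::tibble(cell = rep(paste0("c", 1:200), each = 20),
                         bin_id = rep(paste0("b", 1:20), 200),
                         value = rnorm(n, 2, 0.5))
  truth <- tibble::tibble(bin_id = paste0("b", 1:20), copy = 2)
  ss <- cnv_sensitivity_specificity(vals, truth)
  p <- 2 * pnorm(1) - 1
  expect_lt(abs(ss$specificity - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("average-linkage clustering separates subclones deterministically", {
  mk <- function(profile, cells) {
    tidyr::expand_grid(cell = cells, bin_id = paste0("b", seq_along(profile))) |>
      dplyr::mutate(value = rep(profile, length(cells)))
  }
  vals <- dplyr::bind_rows(mk(c(2, 2, 3, 3), paste0("a", 1:4)),
                           mk(c(2, 2, 1, 1), paste0("b", 1:5)))
  cl <- cluster_cells(vals, k = 2)
  truth <- c(rep(1, 4), rep(2, 5))
  expect_equal(ari(cl$labels$cluster, truth), 1)

  # permuting input order leaves the partition unchanged
  perm <- vals[sample(seq_len(nrow(vals))), ]
  cl2 <- cluster_cells(perm, k = 2)
  joined <- dplyr::inner_join(cl$labels, cl2$labels, by = "cell")
  expect_equal(ari(joined$cluster.x, joined$cluster.y), 1)

  ident <- mk(c(2, 2, 2, 2), paste0("c", 1:4))
  cl3 <- cluster_cells(ident, k = 2)
  expect_equal(unique(cl3$labels$cluster), 1L)
})

test_that("ari matches mclust's adjusted Rand index", {
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b))
  }
})

test_that("low-coverage bins are masked by the median rule", {
  bins <- build_bins(c(chr1 = 5e7), 1e7)
  bins$n_fragments <- c(1000L, 900L, 1100L, 50L, 1000L)
  masked <- mask_low_coverage_bins(bins)
  expect_equal(masked$masked, c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("fine-bin refinement localizes a planted sub-bin gain", {
  fine <- build_bins(c(chr1 = 2e7), 1e6)  # 20 x 2-Mb-scale fine bins
  fine$n_fragments <- rep(100L, 20)
  ctrl <- tibble::tibble(bin_id = fine$bin_id, depth = rep(50, 20))
  depth <- tibble::tibble(cell = "c", bin_id = fine$bin_id,
                          depth = rep(40, 20))
  gain_bins <- 9:10  # a 2-Mb gain inside what a 10-Mb bin would average away
  depth$depth[gain_bins] <- 80
  out <- refine_cnv_segments(depth, ctrl, fine, min_fragments = 20,
                             stay_prob = 0.99)
  seg <- out$segments[out$segments$state == 4, ]
  expect_equal(nrow(seg), 1L)
  expect_lte(abs(seg$start - fine$start[9]), 1e6)
  expect_lte(abs(seg$end - fine$end[10]), 1e6)

  # uniform coverage: a single diploid segment
  flat <- dplyr::mutate(depth, depth = 40)
  out2 <- refine_cnv_segments(flat, ctrl, fine, min_fragments = 20)
  expect_equal(nrow(out2$segments), 1L)
  expect_equal(out2$segments$state, 2L)

  fine_low <- dplyr::mutate(fine, n_fragments = 5L)
  expect_warning(out3 <- refine_cnv_segments(depth, ctrl, fine_low,
                                             min_fragments = 20),
                 "threshold")
  expect_equal(nrow(out3$segments), 0L)
})

test_that("library scaling leaves HMM states unchanged", {
  fix <- small_sim(seed = 31)
  bins <- count_fragments_per_bin(fix$ann$fragments, fix$ann$bins,
                                  unique_only = TRUE)
  bins <- mask_low_coverage_bins(bins)
  f <- normalization_factors(fix$sim$control, bins)
  v1 <- normalize_bins(fix$sim$bin_depth, f)
  scaled_depth <- dplyr::mutate(fix$sim$bin_depth, depth = depth * 3.7)
  v2 <- normalize_bins(scaled_depth, f)
  expect_equal(v1$value, v2$value)
  expect_equal(fit_cnv_hmm(v1, bins)$profile$state,
               fit_cnv_hmm(v2, bins)$profile$state)
})

test_that("gain-in-one-bin normalization matches the planted construction", {
  # fragment-capture rates scale with copy/2, so a copy-4 bin doubles depth
  ann <- simulate_annotation(n_chrom = 2, frags_per_bin = 800,
                             genes_per_bin = 5, seed = 41)
  cfg <- sim_config(subpops = list(
    A = list(n_cells = 20, events = list(
      list(chrom = "chr1", start = 0, end = 1e7, copy = 4))),
    B = list(n_cells = 2, events = list())))
  sim <- simulate_population(cfg, ann, seed = 42)
  bins <- count_fragments_per_bin(ann$fragments, ann$bins, unique_only = TRUE)
  vals <- normalize_bins(sim$bin_depth,
                         normalization_factors(sim$control, bins))
  cells_a <- sim$truth$cells$cell[sim$truth$cells$subpop == "A"]
  va <- vals[vals$cell %in% cells_a, ]
  target <- ann$bins$bin_id[1]
  # library renormalization: value = 2 * copy / mean(copy over bins)
  mean_copy <- (4 + 7 * 2) / 8
  expect_lt(abs(mean(va$value[va$bin_id == target]) - 2 * 4 / mean_copy),
            0.1)
  expect_lt(abs(mean(va$value[va$bin_id != target]) - 2 * 2 / mean_copy),
            0.05)
})
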