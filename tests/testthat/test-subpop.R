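make_cgi_calls <- function(cell, cgi_start, n_cpgs, n_meth) {
  make_level_calls(cell, "chr1", cgi_start + seq_len(n_cpgs) * 10L,
                   c(rep(1, n_meth), rep(0, n_cpgs - n_meth)))
}

two_group_labels <- function(n1, n2) {
  tibble::tibble(cell = c(sprintf("I_%02d", seq_len(n1)),
                          sprintf("II_%02d", seq_len(n2))),
                 subpop = rep(c("I", "II"), c(n1, n2)))
}

test_that("CGI pooling enforces per-cell and per-subpopulation minimums", {
  cgis <- tibble::tibble(cgi_id = "cgi1", chrom = "chr1",
                         start = 0L, end = 1000L)
  labels <- two_group_labels(7, 18)

  # 4 detected CpGs in one cell: not qualified; subpop II fully covered
  calls <- dplyr::bind_rows(
    make_cgi_calls("I_01", 0L, 4, 2),
    purrr::map_dfr(labels$cell[8:25], make_cgi_calls,
                   cgi_start = 0L, n_cpgs = 6, n_meth = 3))
  pooled <- pool_cgi_counts(calls, cgis, labels)
  expect_false("I" %in% pooled$subpop)
  expect_true("II" %in% pooled$subpop)

  # qualified in 2 of 7 cells: below the 3-of-7 minimum
  calls2 <- purrr::map_dfr(labels$cell[1:2], make_cgi_calls,
                           cgi_start = 0L, n_cpgs = 6, n_meth = 6)
  expect_equal(nrow(pool_cgi_counts(dplyr::bind_rows(calls2, calls), cgis,
                                    labels) |>
                      dplyr::filter(subpop == "I")), 0L)

  # 3 of 7 qualifies; counts add: (3,2) + (1,4) + (6,0) -> (10,6)
  calls3 <- dplyr::bind_rows(
    make_cgi_calls("I_01", 0L, 5, 3),
    make_cgi_calls("I_02", 0L, 5, 1),
    make_cgi_calls("I_03", 0L, 6, 6),
    calls[calls$cell != "I_01", ])
  pooled3 <- pool_cgi_counts(calls3, cgis, labels)
  row_i <- pooled3[pooled3$subpop == "I", ]
  expect_equal(row_i$mcg, 3 + 1 + 6)
  expect_equal(row_i$umcg, 2 + 4 + 0)
  expect_equal(row_i$n_qualified, 3L)

  # the fractional rule reproduces 5-of-18 for the larger subpopulation
  calls4 <- purrr::map_dfr(labels$cell[8:11], make_cgi_calls,
                           cgi_start = 0L, n_cpgs = 6, n_meth = 3)
  expect_equal(nrow(pool_cgi_counts(calls4, cgis, labels)), 0L)
  calls5 <- dplyr::bind_rows(calls4,
                             make_cgi_calls("II_05", 0L, 6, 3))
  expect_equal(pool_cgi_counts(calls5, cgis, labels)$n_qualified, 5L)

  one_group <- dplyr::mutate(labels, subpop = "I")
  expect_error(pool_cgi_counts(calls, cgis, one_group), "2 subpop")
})

test_that("dmCGI calls require both significance and effect size", {
  pooled <- tibble::tibble(
    cgi_id = c("a", "a", "b", "b", "c", "c"),
    subpop = rep(c("I", "II"), 3),
    mcg = c(10, 0, 5, 5, 30, 29),
    umcg = c(0, 10, 5, 5, 70, 71),
    n_qualified = 3L, qualified = TRUE)
  out <- call_dmcgi(pooled)
  expect_equal(out$cgi_id, "a")
  expect_equal(out$difference, 1)
  expect_equal(out$direction, "hyper-I")
  expect_equal(out$p, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  # "b": identical pools; "c": difference 0.01 < 0.3 regardless of p
})

test_that("dmCGI calling is antisymmetric in the subpopulation labels", {
  set.seed(21)
  pooled <- purrr::map_dfr(1:12, function(i) {
    tibble::tibble(cgi_id = sprintf("cgi%02d", i),
                   subpop = c("I", "II"),
                   mcg = rpois(2, 20), umcg = rpois(2, 20),
                   n_qualified = 4L, qualified = TRUE)
  })
  fwd <- call_dmcgi(pooled, groups = c("I", "II"), min_diff = 0.05,
                    alpha = 0.5)
  rev <- call_dmcgi(pooled, groups = c("II", "I"), min_diff = 0.05,
                    alpha = 0.5)
  expect_equal(fwd$cgi_id, rev$cgi_id)
  expect_equal(fwd$p, rev$p)
  # the signed difference flips; the hypermethylated-subpop label is stable
  expect_equal(fwd$difference, -rev$difference)
  expect_equal(fwd$direction, rev$direction)
})

test_that("Fisher p-values equal hypergeometric enumeration on random tables", {
  set.seed(8)
  for (i in 1:50) {
    tab <- as.vector(stats::rmultinom(1, sample(10:200, 1), runif(4, 0.1, 1)))
    p_pkg <- fisher.test(matrix(tab, nrow = 2))$p.value
    expect_equal(p_pkg, oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("differential expression recovers planted fold changes", {
  set.seed(5)
  n_genes <- 300
  up_genes <- paste0("g", 1:20)
  cells <- c(paste0("a", 1:10), paste0("b", 1:10))
  labels <- tibble::tibble(cell = cells,
                           subpop = rep(c("I", "II"), each = 10))
  base <- rlnorm(n_genes, log(8), 1)
  expr <- purrr::map_dfr(cells, function(cl) {
    mu <- base
    if (substr(cl, 1, 1) == "a") mu[1:20] <- mu[1:20] * 4
    tibble::tibble(gene_id = paste0("g", 1:n_genes), cell = cl,
                   fpkm = rlnorm(n_genes, log(mu), 0.4))
  })
  de <- differential_expression(expr, labels)
  up_called <- de$gene_id[!is.na(de$direction) & de$direction == "up"]
  expect_gte(mean(up_genes %in% up_called), 0.9)
  false_calls <- setdiff(de$gene_id[!is.na(de$direction)], up_genes)
  expect_lte(length(false_calls), 0.05 * n_genes)

  # constant gene gets p = 1
  const <- tibble::tibble(gene_id = "flat", cell = cells, fpkm = 5)
  de2 <- differential_expression(dplyr::bind_rows(expr, const), labels)
  expect_equal(de2$p[de2$gene_id == "flat"], 1)
})

test_that("null differential expression is calibrated", {
  set.seed(6)
  cells <- c(paste0("a", 1:8), paste0("b", 1:8))
  labels <- tibble::tibble(cell = cells,
                           subpop = rep(c("I", "II"), each = 8))
  expr <- purrr::map_dfr(cells, function(cl) {
    tibble::tibble(gene_id = paste0("g", 1:400), cell = cl,
                   fpkm = rlnorm(400, log(8), 0.5))
  })
  de <- differential_expression(expr, labels)
  expect_lte(sum(!is.na(de$direction)), 0.05 * 400)
  # p-values roughly uniform: around half below 0.5
  expect_lt(abs(mean(de$p < 0.5) - 0.5), 0.12)
})

test_that("PCA separates subclones with deterministic sign conventions", {
  genes <- paste0("g", 1:40)
  cells <- paste0("c", 1:10)
  base <- matrix(8, nrow = 40, ncol = 10)
  base[1:10, 6:10] <- 64  # second subclone overexpresses a gene block
  expr <- tibble::tibble(gene_id = rep(genes, times = 10),
                         cell = rep(cells, each = 40),
                         fpkm = as.vector(base))
  pca <- pca_cells(expr)
  pc1 <- pca$coords$PC1
  expect_true(max(pc1[1:5]) < min(pc1[6:10]) ||
                min(pc1[1:5]) > max(pc1[6:10]))

  # duplicated cell lands on identical coordinates
  dup <- dplyr::bind_rows(expr,
                          dplyr::mutate(expr[expr$cell == "c1", ],
                                        cell = "c1_copy"))
  pd <- pca_cells(dup)
  expect_equal(unlist(pd$coords[pd$coords$cell == "c1", -1]),
               unlist(pd$coords[pd$coords$cell == "c1_copy", -1]))

  # rotation is orthonormal
  rot <- pca$fit$rotation
  expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("copy-value correlations behave on constructed profiles", {
  prof <- tibble::tibble(cell = "c1", bin_id = paste0("b", 1:6),
                         state = c(1, 2, 2, 3, 3, 4))
  wexpr <- tibble::tibble(cell = "c1", bin_id = paste0("b", 1:6),
                          value = c(1, 2, 2, 3, 3, 4) * 0.5 - 1)
  expect_equal(copy_expression_cor(prof, wexpr)$r, 1)

  flat <- dplyr::mutate(prof, state = 2)
  expect_warning(out <- copy_expression_cor(flat, wexpr), "undefined")
  expect_true(is.na(out$r))

  meth <- dplyr::mutate(wexpr, value = c(1, 2, 2, 3, 3, 4))
  expect_equal(copy_methylation_cor(prof, meth)$r, 1)
  const_meth <- dplyr::mutate(wexpr, value = 0.7)
  expect_warning(out2 <- copy_methylation_cor(prof, const_meth), "undefined")
  expect_true(is.na(out2$r))
})
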