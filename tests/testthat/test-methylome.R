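test_that("CpG call filter applies depth and confidence bounds exactly", {
  calls <- make_calls("c1", "chr1", c(100, 200, 300, 400, 500),
                      meth = c(5, 2, 1, 0, 9),
                      unmeth = c(0, 2, 1, 4, 1))
  out <- filter_cpg_calls(calls)
  # (5,0): kept, level 1; (2,2): level 0.5 dropped; (1,1): depth 2 dropped;
  # (0,4): kept, level 0; (9,1): level 0.9 kept
  expect_equal(out$pos, c(100L, 400L, 500L))
  expect_equal(out$call, c(1L, 0L, 1L))
  expect_equal(out$level, c(1, 0, 1))
  expect_error(filter_cpg_calls(calls, low = 0.9, high = 0.1), "low")

  bulk <- filter_cpg_calls(calls, binarize = FALSE)
  expect_equal(bulk$level, c(1, 0.5, 0, 0.9))
})

test_that("region methylation means detected sites and enforces min CpGs", {
  region <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                           start = 0L, end = 1000L)
  calls6 <- make_level_calls("c1", "chr1", seq(100, 600, by = 100),
                             level = rep(1, 6))
  expect_equal(region_methylation(calls6, region)$level, 1)

  calls5 <- calls6[1:5, ]
  expect_equal(nrow(region_methylation(calls5, region, min_cpgs = 6)), 0L)

  mixed <- make_level_calls("c1", "chr1", seq(100, 600, by = 100),
                            level = c(0, 0, 1, 1, 1, 1))
  expect_equal(region_methylation(mixed, region)$level, 2 / 3)

  # invariant to input order
  shuffled <- mixed[c(4, 1, 6, 3, 2, 5), ]
  expect_equal(region_methylation(shuffled, region)$level, 2 / 3)
})

test_that("promoter regions are strand-aware and clipped", {
  genes <- tibble::tibble(gene_id = c("p", "m", "edge"),
                          chrom = "chr1",
                          tss = c(10000L, 10000L, 300L),
                          tes = c(20000L, 2000L, 5300L),
                          strand = c("+", "-", "+"))
  pr <- promoter_regions(genes)
  expect_equal(pr$start[1], 9000)
  expect_equal(pr$end[1], 10500)
  expect_equal(pr$start[2], 9500)
  expect_equal(pr$end[2], 11000)
  expect_equal(pr$start[3], 0)
})

test_that("gene bodies exclude the promoter-proximal region and CGIs", {
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 0L,
                         tes = 10000L, strand = "+")
  gb <- gene_body_regions(gene, cgis = NULL)
  expect_equal(gb$start, 2000L)
  expect_equal(gb$end, 10000L)

  cgi <- tibble::tibble(chrom = "chr1", start = 4000L, end = 5000L)
  gb2 <- gene_body_regions(gene, cgi)
  expect_equal(gb2$start, c(2000L, 5000L))
  expect_equal(gb2$end, c(4000L, 10000L))

  short <- tibble::tibble(gene_id = "s", chrom = "chr1", tss = 0L,
                          tes = 1500L, strand = "+")
  expect_equal(nrow(gene_body_regions(short)), 0L)

  # minus-strand gene: exclusion runs downstream of the TSS, i.e. leftward
  minus <- tibble::tibble(gene_id = "m", chrom = "chr1", tss = 10000L,
                          tes = 0L, strand = "-")
  gbm <- gene_body_regions(minus)
  expect_equal(gbm$start, 0L)
  expect_equal(gbm$end, 8000L)
})

test_that("metagene fractions partition CpGs and reproduce flat profiles", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          tss = c(50000L, 200000L),
                          tes = c(90000L, 160000L),
                          strand = c("+", "-"))
  set.seed(42)
  pos <- sort(sample(20000:230000, 400))
  calls <- make_level_calls("c1", "chr1", pos, level = rep(0.8, 400))
  prof <- metagene_profile(calls, genes)
  expect_equal(nrow(prof), 30L)
  got <- prof$level[!is.na(prof$level)]
  expect_true(all(abs(got - 0.8) < 1e-12))

  # partition: every CpG inside the extended interval lands in exactly 1 bin
  for (i in 1:2) {
    g <- genes[i, ]
    lo <- min(g$tss, g$tes) - 15000
    hi <- max(g$tss, g$tes) + 15000
    inside <- sum(pos - 1 >= lo & pos - 1 < hi)
    per_gene <- trioscope:::metagene_gene_fractions(calls, g)
    expect_equal(sum(per_gene$n_cpgs), inside)
  }

  # single CpG appears in exactly one fraction
  one <- make_level_calls("c1", "chr1", 60000L, 1)
  pg <- trioscope:::metagene_gene_fractions(one, genes[1, ])
  expect_equal(nrow(pg), 1L)
  expect_equal(sum(pg$n_cpgs), 1L)
})

test_that("a constructed TSS valley shows up in the metagene profile", {
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 50000L,
                         tes = 90000L, strand = "+")
  prom_pos <- seq(49000, 50400, by = 100)
  body_pos <- seq(60000, 89000, by = 500)
  calls <- dplyr::bind_rows(
    make_level_calls("c1", "chr1", prom_pos, rep(0.05, length(prom_pos))),
    make_level_calls("c1", "chr1", body_pos, rep(0.9, length(body_pos))))
  prof <- metagene_profile(calls, gene)
  tss_frac <- prof$level[prof$fraction %in% 5:6]
  mid_body <- prof$level[prof$fraction %in% 12:20]
  expect_true(all(tss_frac[!is.na(tss_frac)] < 0.3))
  expect_true(all(mid_body[!is.na(mid_body)] > 0.7))
})

test_that("methylation-expression correlation handles affine relations", {
  n <- 30
  fpkm <- 2^(seq(0, 6, length.out = n)) - 1
  level_up <- seq(0.1, 0.9, length.out = n)
  meth <- tibble::tibble(region_id = paste0("g", 1:n), level = level_up)
  expr <- tibble::tibble(gene_id = paste0("g", 1:n), fpkm = fpkm)
  expect_equal(methylation_expression_cor(meth, expr)$r, 1)

  meth_dn <- dplyr::mutate(meth, level = rev(level))
  expect_equal(methylation_expression_cor(meth_dn, expr)$r, -1)

  expect_warning(
    r2 <- methylation_expression_cor(meth[1:2, ], expr[1:2, ]),
    "undefined")
  expect_true(is.na(r2$r))
})

test_that("planted couplings give the expected correlation signs", {
  # 5 chromosomes x 100 genes = 500 genes
  ann <- simulate_annotation(n_chrom = 5, frags_per_bin = 400,
                             genes_per_bin = 25, seed = 17)
  cfg <- sim_config(subpops = list(
    A = list(n_cells = 6, events = list()),
    B = list(n_cells = 6, events = list())),
    variable_cgi_fraction = 0)
  sim <- simulate_population(cfg, ann, seed = 18)
  fcalls <- filter_cpg_calls(sim$calls)
  prom <- promoter_regions(ann$genes, sizes = ann$chrom_sizes)
  body <- gene_body_regions(ann$genes, ann$cgis)
  r_prom <- methylation_expression_cor(
    region_methylation(fcalls, prom), sim$expression)
  r_body <- methylation_expression_cor(
    region_methylation(fcalls, body), sim$expression)
  expect_true(all(r_prom$r < 0))
  expect_true(all(r_body$r > 0))

  # per-fraction curve: negative near the TSS, positive in the distal body
  cell1 <- fcalls[fcalls$cell == fcalls$cell[1], ]
  expr1 <- sim$expression[sim$expression$cell == fcalls$cell[1], ]
  curve <- fraction_expression_cor(cell1, ann$genes, expr1)
  tss_r <- curve$r[curve$fraction == 6]
  distal <- curve$r[curve$zone == "body" & curve$fraction >= 15]
  expect_lt(tss_r, 0)
  expect_gt(mean(distal, na.rm = TRUE), 0)
})

test_that("pairwise cell correlation uses co-detected sites only", {
  a <- make_level_calls("a", "chr1", 1:20 * 100, rep(c(0, 1), 10))
  b <- dplyr::mutate(a, cell = "b")
  out <- pairwise_cell_cor(dplyr::bind_rows(a, b))
  expect_equal(out$r, 1)
  expect_equal(out$n_sites, 20L)

  compl <- dplyr::mutate(a, cell = "b", call = 1L - call,
                         level = 1 - level)
  out2 <- pairwise_cell_cor(dplyr::bind_rows(a, compl))
  expect_equal(out2$r, -1)

  disjoint <- dplyr::mutate(a, cell = "b", pos = pos + 5L)
  out3 <- pairwise_cell_cor(dplyr::bind_rows(a, disjoint))
  expect_true(is.na(out3$r))

  # symmetric in its arguments: same result with cells renamed/swapped
  swapped <- dplyr::bind_rows(dplyr::mutate(a, cell = "b"),
                              dplyr::mutate(compl, cell = "a"))
  expect_equal(pairwise_cell_cor(swapped)$r, out2$r)
})

test_that("global methylation restricts to mask regions like a subset oracle", {
  calls <- make_level_calls("c1", "chr1", 1:50 * 1000,
                            rep(c(1, 1, 0, 1, 0), 10))
  expect_equal(global_methylation(calls)$level, 0.6)

  mask <- tibble::tibble(chrom = "chr1", start = 0L, end = 25500L)
  direct <- mean(calls$level[calls$pos <= 25500])
  expect_equal(global_methylation(calls, mask)$level, direct)

  empty_mask <- tibble::tibble(chrom = "chr2", start = 0L, end = 100L)
  expect_true(is.na(global_methylation(calls, empty_mask)$level))
})
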