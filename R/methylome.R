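#' Filter single-cell CpG calls to confident binary states
#'
#' Single-cell RRBS calls are trustworthy only when deeply covered and nearly
#' homogeneous, so sites are kept when depth >= `min_depth` and the methylation
#' ratio is <= `low` or >= `high`; retained sites are binarized (`call` 0/1).
#' Bulk data should skip this filter and work with raw ratios (see
#' `binarize = FALSE`).
#'
#' @param calls tibble with `chrom`, `pos` (1-based CpG cytosine), `meth`,
#'   `unmeth` counts and an optional `cell` column.
#' @param min_depth minimum read depth (default 3).
#' @param low,high methylation-ratio bounds for confident unmethylated /
#'   methylated states (defaults 0.1 and 0.9); `low` must be below `high`.
#' @param binarize if `FALSE`, only the depth filter is applied and `level`
#'   keeps the raw ratio (bulk mode).
#' @return The filtered tibble with `depth`, `level` and (single-cell mode)
#'   binary `call` columns added.
#' @export
filter_cpg_calls <- function(calls, min_depth = 3, low = 0.1, high = 0.9,
                             binarize = TRUE) {
  check_columns(calls, c("chrom", "pos", "meth", "unmeth"), "calls")
  if (low >= high) stop_trio("low must be smaller than high")
  if (any(calls$meth < 0 | calls$unmeth < 0)) {
    stop_trio("negative read counts in calls")
  }
  out <- dplyr::mutate(calls,
                       depth = .data$meth + .data$unmeth,
                       level = .data$meth / .data$depth)
  out <- dplyr::filter(out, .data$depth >= min_depth)
  if (binarize) {
    out <- dplyr::filter(out, .data$level <= low | .data$level >= high)
    out <- dplyr::mutate(out, call = as.integer(.data$level >= high),
                         level = as.numeric(.data$call))
  }
  out
}

#' Promoter interval of a gene
#'
#' The promoter spans 1000 bp upstream to 500 bp downstream of the TSS along
#' the direction of transcription, clipped at chromosome ends when sizes are
#' supplied. Coordinates are 0-based half-open.
#'
#' @param genes tibble `gene_id`, `chrom`, `tss`, `strand`.
#' @param upstream,downstream extent around the TSS in bp.
#' @param sizes optional chromosome sizes tibble (`chrom`, `size`) for
#'   clipping.
#' @return Tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_regions <- function(genes, upstream = 1000, downstream = 500,
                             sizes = NULL) {
  check_columns(genes, c("gene_id", "chrom", "tss", "strand"), "genes")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  out <- tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = pmax(start, 0), end = end)
  if (!is.null(sizes)) {
    out <- dplyr::left_join(out, sizes, by = "chrom")
    out <- dplyr::mutate(out, end = pmin(.data$end, .data$size), size = NULL)
  }
  out
}

#' Gene-body intervals with promoter and CGI regions removed
#'
#' The gene body runs from TSS to TES; the first 2000 bp downstream of the TSS
#' (the promoter-proximal region) and any overlapping CpG-island intervals are
#' excluded because their methylation behaves differently from the distal
#' body. The result may be empty for short genes.
#'
#' @param genes tibble `gene_id`, `chrom`, `tss`, `tes`, `strand`.
#' @param cgis CpG-island tibble `chrom`, `start`, `end` (0-based half-open);
#'   may be `NULL`.
#' @param promoter_excl bp downstream of the TSS to exclude (default 2000).
#' @return Tibble `gene_id`, `chrom`, `start`, `end`, possibly several rows
#'   per gene, genes with empty bodies absent.
#' @export
gene_body_regions <- function(genes, cgis = NULL, promoter_excl = 2000) {
  check_columns(genes, c("gene_id", "chrom", "tss", "tes", "strand"), "genes")
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    lo <- min(g$tss, g$tes)
    hi <- max(g$tss, g$tes)
    body <- IRanges::IRanges(lo + 1L, hi)  # 1-based closed internally
    excl_start <- if (g$strand == "+") g$tss else g$tss - promoter_excl
    excl <- IRanges::IRanges(excl_start + 1L, excl_start + promoter_excl)
    if (!is.null(cgis)) {
      cg <- cgis[cgis$chrom == g$chrom, ]
      if (nrow(cg) > 0L) {
        excl <- c(excl, IRanges::IRanges(cg$start + 1L, cg$end))
      }
    }
    kept <- IRanges::setdiff(body, IRanges::reduce(excl))
    if (length(kept) == 0L) return(NULL)
    tibble::tibble(gene_id = g$gene_id, chrom = g$chrom,
                   start = BiocGenerics::start(kept) - 1L,
                   end = BiocGenerics::end(kept))
  })
}

# Long join of calls against (possibly multi-interval) regions.
calls_in_regions <- function(calls, regions, region_key = "gene_id") {
  purrr::map_dfr(unique(regions$chrom), function(chr) {
    cl <- calls[calls$chrom == chr, ]
    rg <- regions[regions$chrom == chr, ]
    if (nrow(cl) == 0L || nrow(rg) == 0L) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(cl$pos, cl$pos),
      IRanges::IRanges(rg$start + 1L, rg$end))
    out <- cl[S4Vectors::queryHits(hits), ]
    out$region_id <- rg[[region_key]][S4Vectors::subjectHits(hits)]
    out
  })
}

#' Region-level methylation from detected CpGs
#'
#' The methylation level of a region is the unweighted mean of the per-site
#' levels of its detected CpGs; it is undefined (absent) unless at least
#' `min_cpgs` sites are detected. With default `min_cpgs = 6` a region needs
#' more than five detected CpGs, the rule used for promoter / gene-body
#' methylation; CpG-island qualification uses `min_cpgs = 5`.
#'
#' @param calls filtered calls (with `level`) from [filter_cpg_calls()],
#'   optionally per `cell`.
#' @param regions tibble `chrom`, `start`, `end` plus an id column.
#' @param min_cpgs minimum detected CpGs for a defined level.
#' @param region_key name of the id column in `regions`.
#' @return Tibble (`cell`,) `region_id`, `n_cpgs`, `level`.
#' @export
region_methylation <- function(calls, regions, min_cpgs = 6,
                               region_key = "gene_id") {
  check_columns(calls, c("chrom", "pos", "level"), "calls")
  has_cell <- "cell" %in% names(calls)
  if (!has_cell) calls$cell <- "sample"
  hits <- calls_in_regions(calls, regions, region_key)
  if (nrow(hits) == 0L) {
    out <- tibble::tibble(cell = character(), region_id = character(),
                          n_cpgs = integer(), level = numeric())
    if (!has_cell) out$cell <- NULL
    return(out)
  }
  out <- hits |>
    dplyr::group_by(.data$cell, .data$region_id) |>
    dplyr::summarise(n_cpgs = dplyr::n(), level = mean(.data$level),
                     .groups = "drop") |>
    dplyr::filter(.data$n_cpgs >= min_cpgs)
  if (!has_cell) out$cell <- NULL
  out
}

# Fraction index (1..n_flank + n_body + n_flank) of positions relative to a
# gene, strand-aware; NA outside the extended interval.
metagene_fraction <- function(pos, tss, tes, strand, n_body, n_flank,
                              flank_bp) {
  dir <- ifelse(strand == "+", 1, -1)
  d <- (pos - 1 - tss) * dir          # 0-based offset along transcription
  len <- abs(tes - tss)
  fw <- flank_bp / n_flank
  frac <- rep(NA_real_, length(pos))
  up <- d < 0 & d >= -flank_bp
  frac[up] <- floor((d[up] + flank_bp) / fw) + 1
  body <- d >= 0 & d < len
  frac[body] <- n_flank +
    pmin(floor(d[body] / len[body] * n_body), n_body - 1) + 1
  down <- d >= len & d < len + flank_bp
  frac[down] <- n_flank + n_body + pmin(floor((d[down] - len[down]) / fw),
                                        n_flank - 1) + 1
  as.integer(frac)
}

#' Metagene methylation profile
#'
#' Divides every gene body (TSS to TES) into `n_body` equal fractions and each
#' 15-kb flank into `n_flank` fractions, assigns each detected CpG of a cell to
#' exactly one fraction of its gene (strand-aware), and averages: first within
#' gene, then across genes. The default 5 + 20 + 5 layout gives the familiar
#' 30-point profile with the hypomethylation valley at the TSS.
#'
#' @param calls filtered calls with `level` (one cell, or pooled).
#' @param genes tibble `gene_id`, `chrom`, `tss`, `tes`, `strand`.
#' @param n_body,n_flank number of body / flank fractions (>= 1).
#' @param flank_bp flank width in bp.
#' @return Tibble `fraction` (1..n), `zone` (upstream/body/downstream),
#'   `level` (NA where no gene has data), `n_genes`.
#' @export
metagene_profile <- function(calls, genes, n_body = 20, n_flank = 5,
                             flank_bp = 15000) {
  check_number(n_body, "n_body", min = 1)
  check_number(n_flank, "n_flank", min = 1)
  check_columns(calls, c("chrom", "pos", "level"), "calls")
  per_gene <- metagene_gene_fractions(calls, genes, n_body, n_flank, flank_bp)
  n_tot <- n_body + 2 * n_flank
  zone <- rep(c("upstream", "body", "downstream"),
              c(n_flank, n_body, n_flank))
  agg <- per_gene |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(level = mean(.data$level), n_genes = dplyr::n(),
                     .groups = "drop")
  out <- tibble::tibble(fraction = seq_len(n_tot), zone = zone)
  out <- dplyr::left_join(out, agg, by = "fraction")
  dplyr::mutate(out, n_genes = tidyr::replace_na(.data$n_genes, 0L))
}

# Per-gene per-fraction mean levels (the partition level of the metagene).
metagene_gene_fractions <- function(calls, genes, n_body = 20, n_flank = 5,
                                    flank_bp = 15000) {
  joined <- purrr::map_dfr(unique(genes$chrom), function(chr) {
    cl <- calls[calls$chrom == chr, ]
    g <- genes[genes$chrom == chr, ]
    if (nrow(cl) == 0L || nrow(g) == 0L) return(NULL)
    lo <- pmin(g$tss, g$tes) - flank_bp
    hi <- pmax(g$tss, g$tes) + flank_bp
    hits <- IRanges::findOverlaps(IRanges::IRanges(cl$pos, cl$pos),
                                  IRanges::IRanges(lo + 1L, hi))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    tibble::tibble(gene_id = g$gene_id[si], level = cl$level[qi],
                   fraction = metagene_fraction(cl$pos[qi], g$tss[si],
                                                g$tes[si], g$strand[si],
                                                n_body, n_flank, flank_bp))
  })
  joined <- dplyr::filter(joined, !is.na(.data$fraction))
  joined |>
    dplyr::group_by(.data$gene_id, .data$fraction) |>
    dplyr::summarise(level = mean(.data$level), n_cpgs = dplyr::n(),
                     .groups = "drop")
}

#' Correlation between region methylation and gene expression
#'
#' Pearson correlation between region-level methylation (promoter or gene
#' body) and `log2(FPKM + 1)` over genes with both values defined. FPKM below
#' 0.001 is reset to 0.001 before the transform. With fewer than `min_pairs`
#' genes the correlation is undefined (NA with a warning).
#'
#' @param meth tibble `region_id` (gene id), `level`, optionally per `cell`.
#' @param expr tibble `gene_id`, `fpkm`, optionally per `cell`.
#' @param min_pairs minimum paired genes (default 3).
#' @param ranked also compute the correlation on expression-ranked values
#'   (Spearman-style variant; reported as `r_ranked`).
#' @return One row per cell (or a single row): `n_genes`, `r`, and `r_ranked`
#'   if requested.
#' @export
methylation_expression_cor <- function(meth, expr, min_pairs = 3,
                                       ranked = FALSE) {
  check_columns(meth, c("region_id", "level"), "meth")
  check_columns(expr, c("gene_id", "fpkm"), "expr")
  by_cell <- "cell" %in% names(meth) && "cell" %in% names(expr)
  if (!by_cell) {
    meth$cell <- "sample"
    expr$cell <- "sample"
  }
  joined <- dplyr::inner_join(meth,
                              dplyr::rename(expr, region_id = "gene_id"),
                              by = c("cell", "region_id"))
  joined <- dplyr::mutate(joined,
                          logexpr = log2(pmax(.data$fpkm, 0.001) + 1))
  out <- joined |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      r = if (dplyr::n() >= min_pairs) {
        suppressWarnings(cor(.data$level, .data$logexpr))
      } else NA_real_,
      r_ranked = if (ranked && dplyr::n() >= min_pairs) {
        suppressWarnings(cor(.data$level, rank(.data$logexpr)))
      } else NA_real_,
      .groups = "drop")
  if (any(is.na(out$r))) {
    warn("correlation undefined for some cells (fewer than min_pairs genes or zero variance)")
  }
  if (!ranked) out$r_ranked <- NULL
  if (!by_cell) out$cell <- NULL
  out
}

#' Per-fraction methylation-expression correlation curve
#'
#' For each metagene fraction, correlates the per-gene fraction methylation
#' with the gene's expression (`log2(FPKM + 1)`, FPKM < 0.001 reset to 0.001)
#' across genes. On data with promoter-repressive and gene-body-activating
#' couplings the curve is negative near the TSS and positive toward the 3'
#' body.
#'
#' @inheritParams metagene_profile
#' @param expr tibble `gene_id`, `fpkm` for the same cell.
#' @param min_pairs minimum genes per fraction.
#' @return Tibble `fraction`, `zone`, `n_genes`, `r`.
#' @export
fraction_expression_cor <- function(calls, genes, expr, n_body = 20,
                                    n_flank = 5, flank_bp = 15000,
                                    min_pairs = 3) {
  per_gene <- metagene_gene_fractions(calls, genes, n_body, n_flank, flank_bp)
  ex <- dplyr::mutate(expr, logexpr = log2(pmax(.data$fpkm, 0.001) + 1))
  joined <- dplyr::inner_join(per_gene, ex[, c("gene_id", "logexpr")],
                              by = "gene_id")
  n_tot <- n_body + 2 * n_flank
  zone <- rep(c("upstream", "body", "downstream"),
              c(n_flank, n_body, n_flank))
  agg <- joined |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      r = if (dplyr::n() >= min_pairs) {
        suppressWarnings(cor(.data$level, .data$logexpr))
      } else NA_real_, .groups = "drop")
  out <- tibble::tibble(fraction = seq_len(n_tot), zone = zone)
  out <- dplyr::left_join(out, agg, by = "fraction")
  dplyr::mutate(out, n_genes = tidyr::replace_na(.data$n_genes, 0L))
}

#' Pairwise cell-to-cell methylation correlation
#'
#' Pearson correlation of binary methylation calls over the CpG sites
#' co-detected in each pair of cells ("pairwise" handling of missing sites).
#' Pairs with fewer than `min_sites` shared sites, or with zero variance in
#' either cell, are undefined (NA).
#'
#' @param calls filtered binarized calls with `cell`, `chrom`, `pos`, `call`.
#' @param min_sites minimum co-detected sites (default 10).
#' @return Tibble `cell_a`, `cell_b`, `n_sites`, `r` for all unordered pairs.
#' @export
pairwise_cell_cor <- function(calls, min_sites = 10) {
  check_columns(calls, c("cell", "chrom", "pos", "call"), "calls")
  cells <- sort(unique(calls$cell))
  by_cell <- split(calls[, c("chrom", "pos", "call")], calls$cell)
  pairs <- utils::combn(cells, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- by_cell[[pairs[1, j]]]
    b <- by_cell[[pairs[2, j]]]
    m <- dplyr::inner_join(a, b, by = c("chrom", "pos"),
                           suffix = c("_a", "_b"))
    r <- if (nrow(m) >= min_sites) {
      suppressWarnings(cor(m$call_a, m$call_b))
    } else NA_real_
    tibble::tibble(cell_a = pairs[1, j], cell_b = pairs[2, j],
                   n_sites = nrow(m), r = r)
  })
}

#' Global methylation level of a cell
#'
#' Unweighted mean level over detected CpGs, optionally restricted to a set of
#' mask regions (e.g. the regions also detected in another dataset, to make
#' bulk and single-cell values comparable).
#'
#' @param calls calls with `chrom`, `pos`, `level`, optional `cell`.
#' @param mask_regions optional tibble `chrom`, `start`, `end`; only CpGs
#'   inside are used.
#' @return Tibble (`cell`,) `n_cpgs`, `level` (NA when nothing is detected).
#' @export
global_methylation <- function(calls, mask_regions = NULL) {
  check_columns(calls, c("chrom", "pos", "level"), "calls")
  has_cell <- "cell" %in% names(calls)
  if (!has_cell) calls$cell <- "sample"
  if (!is.null(mask_regions)) {
    mask_regions$mask_id <- seq_len(nrow(mask_regions))
    calls <- calls_in_regions(calls, mask_regions, "mask_id")
  }
  if (nrow(calls) == 0L) {
    out <- tibble::tibble(cell = "sample", n_cpgs = 0L, level = NA_real_)
    if (!has_cell) out$cell <- NULL
    return(out)
  }
  out <- calls |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(n_cpgs = dplyr::n(), level = mean(.data$level),
                     .groups = "drop")
  if (nrow(out) == 0L) {
    out <- tibble::tibble(cell = "sample", n_cpgs = 0L, level = NA_real_)
  }
  if (!has_cell) out$cell <- NULL
  out
}
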