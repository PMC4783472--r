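#' Synthetic genome annotation for triple-omics simulations
#'
#' Builds the coordinate backbone of a simulated dataset: toy chromosomes tiled
#' into bins, gene models, promoter CpG islands, and a set of uniquely mappable
#' MspI-fragment stand-ins with CpG positions. RRBS coverage is CpG-biased, so
#' fragments are placed preferentially at promoters/CGIs and in gene bodies,
#' with the remainder scattered as background.
#'
#' @param n_chrom number of autosome-like chromosomes.
#' @param chrom_size chromosome length in bp.
#' @param bin_size copy-number bin width in bp (default 10 Mb).
#' @param frags_per_bin total fragments per bin (gene-linked plus background).
#' @param genes_per_bin gene models per bin.
#' @param gene_length gene length in bp.
#' @param cgi_fraction fraction of promoters carrying a CpG island.
#' @param include_x add a chrX chromosome (used for sensitivity designs where
#'   X is simulated at copy 1).
#' @param seed optional integer seed; caller RNG state is restored.
#' @return An object of class `trio_annotation`: a list of tibbles
#'   `chrom_sizes`, `bins`, `genes`, `cgis`, `fragments`, `cpgs`.
#' @export
simulate_annotation <- function(n_chrom = 10, chrom_size = 4e7, bin_size = 1e7,
                                frags_per_bin = 1200, genes_per_bin = 25,
                                gene_length = 2e4, cgi_fraction = 0.7,
                                include_x = FALSE, seed = NULL) {
  check_number(bin_size, "bin_size", min = 1)
  check_number(frags_per_bin, "frags_per_bin", min = 1)
  with_preserved_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    if (include_x) chroms <- c(chroms, "chrX")
    sizes <- tibble::tibble(chrom = chroms, size = as.integer(chrom_size))
    bins <- build_bins(sizes, bin_size)

    flank <- 16000
    genes <- purrr::map_dfr(chroms, function(chr) {
      n_bins_chr <- sum(bins$chrom == chr)
      n_g <- genes_per_bin * n_bins_chr
      usable <- chrom_size - 2 * (flank + gene_length)
      spacing <- usable / n_g
      anchor <- flank + gene_length + spacing * (seq_len(n_g) - 0.5) +
        round(runif(n_g, -spacing / 4, spacing / 4))
      strand <- sample(c("+", "-"), n_g, replace = TRUE)
      tss <- round(anchor)
      tes <- ifelse(strand == "+", tss + gene_length, tss - gene_length)
      tibble::tibble(gene_id = sprintf("%s_g%03d", chr, seq_len(n_g)),
                     chrom = chr, tss = as.integer(tss),
                     tes = as.integer(tes), strand = strand)
    })

    with_cgi <- runif(nrow(genes)) < cgi_fraction
    dir <- ifelse(genes$strand == "+", 1L, -1L)
    cgi_start <- ifelse(genes$strand == "+", genes$tss - 800, genes$tss - 700)
    cgis <- tibble::tibble(cgi_id = sprintf("cgi_%s", genes$gene_id[with_cgi]),
                           chrom = genes$chrom[with_cgi],
                           start = as.integer(cgi_start[with_cgi]),
                           end = as.integer(cgi_start[with_cgi] + 1500L),
                           gene_id = genes$gene_id[with_cgi])

    # gene-linked fragments: 2 per promoter, 4 in the distal gene body
    frag_len <- 120L
    prom_frags <- purrr::map_dfr(1:2, function(j) {
      off <- round(runif(nrow(genes), 0, 1500 - frag_len))
      start <- ifelse(genes$strand == "+",
                      genes$tss - 1000 + off, genes$tss - 500 + off)
      tibble::tibble(chrom = genes$chrom, start = as.integer(start),
                     gene_id = genes$gene_id, region = "promoter")
    })
    body_frags <- purrr::map_dfr(1:4, function(j) {
      lo <- 2500
      hi <- gene_length - frag_len - 100
      off <- round(runif(nrow(genes), lo, hi))
      start <- genes$tss + dir * off - ifelse(dir == 1L, 0L, frag_len)
      tibble::tibble(chrom = genes$chrom, start = as.integer(start),
                     gene_id = genes$gene_id, region = "body")
    })
    n_gene_frags <- dplyr::count(dplyr::bind_rows(prom_frags, body_frags),
                                 .data$chrom, name = "n_linked")
    bg_frags <- purrr::map_dfr(chroms, function(chr) {
      n_bins_chr <- sum(bins$chrom == chr)
      linked <- n_gene_frags$n_linked[match(chr, n_gene_frags$chrom)]
      n_bg <- max(frags_per_bin * n_bins_chr - linked, 0L)
      tibble::tibble(chrom = chr,
                     start = as.integer(sort(round(runif(n_bg, 100,
                                                         chrom_size - frag_len - 100)))),
                     gene_id = NA_character_, region = "background")
    })
    fragments <- dplyr::bind_rows(prom_frags, body_frags, bg_frags)
    fragments <- dplyr::arrange(fragments, .data$chrom, .data$start)
    fragments <- dplyr::mutate(fragments,
                               end = .data$start + frag_len,
                               frag_id = sprintf("f%06d", dplyr::row_number()),
                               is_unique = TRUE)

    n_cpg <- dplyr::case_match(fragments$region,
                               "promoter" ~ 8L, "body" ~ 5L,
                               "background" ~ 3L)
    cpgs <- tibble::tibble(
      frag_id = rep(fragments$frag_id, n_cpg),
      chrom = rep(fragments$chrom, n_cpg),
      start = rep(fragments$start, n_cpg),
      gene_id = rep(fragments$gene_id, n_cpg),
      region = rep(fragments$region, n_cpg)
    )
    offs <- unlist(lapply(n_cpg, function(k) sort(sample.int(frag_len - 2L, k))))
    cpgs$pos <- as.integer(cpgs$start + offs + 1L)  # 1-based CpG cytosine
    cpgs$start <- NULL
    # CGI membership of promoter CpGs
    cpgs$cgi_id <- NA_character_
    prom <- which(cpgs$region == "promoter" & !is.na(cpgs$gene_id))
    cgi_of_gene <- setNames(cgis$cgi_id, cgis$gene_id)
    hit <- cgi_of_gene[cpgs$gene_id[prom]]
    cg <- cgis[match(hit, cgis$cgi_id), ]
    inside <- !is.na(hit) & cpgs$pos[prom] > cg$start & cpgs$pos[prom] <= cg$end
    cpgs$cgi_id[prom[inside]] <- hit[inside]
    cpgs <- dplyr::arrange(cpgs, .data$chrom, .data$pos)

    fragments <- dplyr::select(fragments, "frag_id", "chrom", "start", "end",
                               "is_unique", "region", "gene_id")
    structure(list(chrom_sizes = sizes, bins = bins, genes = genes,
                   cgis = cgis, fragments = fragments, cpgs = cpgs),
              class = "trio_annotation")
  })
}

#' @export
print.trio_annotation <- function(x, ...) {
  cat("<trio_annotation> ", nrow(x$chrom_sizes), " chromosome(s), ",
      nrow(x$bins), " bins, ", nrow(x$genes), " genes, ",
      nrow(x$cgis), " CGIs, ", nrow(x$fragments), " fragments, ",
      nrow(x$cpgs), " CpGs\n", sep = "")
  invisible(x)
}

#' Simulation configuration
#'
#' Assembles (and validates) the parameter set of the triple-omics simulator.
#' Defaults describe a two-subpopulation tumor similar in structure to the
#' datasets this toolkit targets: both subpopulations share one gained region,
#' subpopulation I carries private gains, subpopulation II a private loss;
#' capture, depth, dropout and dispersion values give the sparse, noisy
#' coverage typical of single-cell RRBS and RNA-seq.
#'
#' @param subpops named list; each element is `list(n_cells=, events=)` where
#'   `events` is a list of `list(chrom=, start=, end=, copy=)` copy-number
#'   events applied on top of the diploid baseline.
#' @param capture_prob probability that a unique fragment is captured in a cell
#'   at copy number 2; scales linearly with copy/2.
#' @param depth_mean mean per-CpG read depth of a captured fragment (Poisson).
#' @param depth_model `"poisson"` or `"fixed"` (deterministic depth, for
#'   noise-free validation runs).
#' @param read_len nominal read length in bp (used to convert read counts into
#'   sequenced bases for bin depth).
#' @param cpg_dropout probability that a covered CpG is lost in a cell.
#' @param expr_meanlog,expr_sdlog_baseline log-normal parameters of gene
#'   baseline (diploid) FPKM means.
#' @param expr_sdlog per-cell log-normal expression dispersion (sdlog scale).
#' @param expr_dropout probability that a gene's FPKM drops out to 0 in a cell.
#' @param coupling_promoter,coupling_body logit-scale coupling of promoter /
#'   gene-body methylation to standardized log-expression (negative promoter
#'   coupling represses; positive body coupling activates).
#' @param prom_intercept,body_intercept logit-scale mean methylation of
#'   promoters (the TSS valley) and gene bodies.
#' @param meth_noise_sd gene-to-gene logit-scale methylation noise.
#' @param variable_cgi_fraction fraction of CGIs whose methylation is bimodal
#'   across cells (drives cell-to-cell variance structure).
#' @param variable_levels the two levels a variable CGI toggles between.
#' @param overdispersion negative-binomial size for per-CpG depth; `Inf`
#'   (default) keeps the Poisson model.
#' @param meth_model `"bernoulli"` (default): each CpG in each cell first
#'   draws a binary methylation state with probability equal to the regional
#'   mean, and reads then report that state up to `meth_error`; this gives the
#'   bimodal per-CpG ratios characteristic of single cells (two alleles).
#'   `"binomial"`: methylated reads are drawn directly as
#'   Binomial(depth, regional mean), a bulk-like mixture.
#' @param meth_error probability that a read contradicts the CpG's state
#'   (conversion/sequencing error) under the Bernoulli model.
#' @param x_copy copy number of chrX bins (all subpopulations) when the
#'   annotation includes chrX.
#' @param meth_copy_coupling logit-scale coupling of methylation to copy
#'   number; 0 (default) keeps methylation independent of CNV, matching the
#'   biology this toolkit is designed to test.
#' @return A list of class `trio_sim_config`.
#' @export
sim_config <- function(subpops = NULL,
                       capture_prob = 0.5, depth_mean = 6,
                       depth_model = c("poisson", "fixed"), read_len = 36,
                       cpg_dropout = 0.1,
                       expr_meanlog = log(8), expr_sdlog_baseline = 1.2,
                       expr_sdlog = 0.5, expr_dropout = 0.15,
                       coupling_promoter = -1.2, coupling_body = 0.8,
                       prom_intercept = -1.7, body_intercept = 1.1,
                       meth_noise_sd = 0.4,
                       variable_cgi_fraction = 0.15,
                       variable_levels = c(0.1, 0.9),
                       overdispersion = Inf,
                       meth_model = c("bernoulli", "binomial"),
                       meth_error = 0.01,
                       x_copy = 1, meth_copy_coupling = 0) {
  depth_model <- match.arg(depth_model)
  meth_model <- match.arg(meth_model)
  if (is.null(subpops)) {
    # two tumor subclones sharing one whole-chromosome gain, each with
    # private whole-chromosome gains and losses; about half the genome
    # differs between the subclones, as in heavily rearranged tumors
    subpops <- list(
      I = list(n_cells = 7, events = list(
        list(chrom = "chr1", start = 0, end = 4e7, copy = 3),
        list(chrom = "chr2", start = 0, end = 4e7, copy = 3),
        list(chrom = "chr4", start = 0, end = 4e7, copy = 3),
        list(chrom = "chr5", start = 0, end = 4e7, copy = 1))),
      II = list(n_cells = 18, events = list(
        list(chrom = "chr1", start = 0, end = 4e7, copy = 3),
        list(chrom = "chr3", start = 0, end = 4e7, copy = 1),
        list(chrom = "chr6", start = 0, end = 4e7, copy = 1))))
  }
  for (p in c(capture_prob, cpg_dropout, expr_dropout, variable_cgi_fraction)) {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop_trio("probabilities must lie in [0, 1]")
    }
  }
  check_number(depth_mean, "depth_mean", min = 0, strict = TRUE)
  if (length(subpops) < 1L || is.null(names(subpops))) {
    stop_trio("subpops must be a named list")
  }
  structure(list(subpops = subpops, capture_prob = capture_prob,
                 depth_mean = depth_mean, depth_model = depth_model,
                 read_len = read_len, cpg_dropout = cpg_dropout,
                 expr_meanlog = expr_meanlog,
                 expr_sdlog_baseline = expr_sdlog_baseline,
                 expr_sdlog = expr_sdlog, expr_dropout = expr_dropout,
                 coupling_promoter = coupling_promoter,
                 coupling_body = coupling_body,
                 prom_intercept = prom_intercept,
                 body_intercept = body_intercept,
                 meth_noise_sd = meth_noise_sd,
                 variable_cgi_fraction = variable_cgi_fraction,
                 variable_levels = variable_levels,
                 overdispersion = overdispersion,
                 meth_model = meth_model, meth_error = meth_error,
                 x_copy = x_copy,
                 meth_copy_coupling = meth_copy_coupling),
            class = "trio_sim_config")
}

subpop_copy_profiles <- function(config, bins) {
  purrr::imap_dfr(config$subpops, function(sp, name) {
    copy <- ifelse(bins$chrom == "chrX", config$x_copy, 2)
    for (ev in sp$events %||% list()) {
      hit <- bins$chrom == ev$chrom & bins$start >= ev$start &
        bins$start < ev$end
      if (!any(hit) && !ev$chrom %in% bins$chrom) {
        stop_trio("copy-number event on unknown chromosome: ", ev$chrom)
      }
      copy[hit] <- ev$copy
    }
    tibble::tibble(subpop = name, bin_id = bins$bin_id, copy = copy)
  })
}

#' Simulate a single-cell triple-omics population
#'
#' Generates, for each cell: RRBS CpG methylation calls (fragment capture with
#' probability `capture_prob * copy/2`, per-CpG Poisson depth, binomial
#' methylated-read counts, CpG dropout), per-bin sequenced-base depth, and
#' gene-level FPKM (log-normal around `baseline * copy/2`, Bernoulli dropout).
#' A diploid bulk control depth profile and a diploid bulk expression reference
#' are included, along with the full ground truth.
#'
#' @param config a [sim_config()] object.
#' @param annotation a [simulate_annotation()] object.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return An object of class `trio_sim`: list with `truth` (class
#'   `trio_truth`), `calls`, `bin_depth`, `capture_counts`, `expression`,
#'   `reference`, `control`, plus the `annotation` and `config` used.
#' @export
simulate_population <- function(config, annotation, seed = 1) {
  stopifnot(inherits(config, "trio_sim_config"),
            inherits(annotation, "trio_annotation"))
  with_preserved_seed(seed, {
    bins <- annotation$bins
    genes <- annotation$genes
    frag <- annotation$fragments
    cpgs <- annotation$cpgs

    profiles <- subpop_copy_profiles(config, bins)
    cells <- purrr::imap_dfr(config$subpops, function(sp, name) {
      tibble::tibble(subpop = name, idx = seq_len(sp$n_cells))
    })
    cells <- dplyr::mutate(cells,
                           cell = sprintf("%s_c%02d", .data$subpop, .data$idx))
    cells <- dplyr::select(cells, "cell", "subpop")
    cnv_truth <- dplyr::inner_join(cells, profiles, by = "subpop",
                                   relationship = "many-to-many")
    cnv_truth <- dplyr::select(cnv_truth, "cell", "bin_id", "copy")

    # --- expression truth and methylation truth ---------------------------
    e_g <- rlnorm(nrow(genes), meanlog = config$expr_meanlog,
                  sdlog = config$expr_sdlog_baseline)
    z <- as.numeric(scale(log2(e_g + 1)))
    prom_m <- stats::plogis(config$prom_intercept +
                              config$coupling_promoter * z +
                              rnorm(length(z), sd = config$meth_noise_sd))
    body_m <- stats::plogis(config$body_intercept +
                              config$coupling_body * z +
                              rnorm(length(z), sd = config$meth_noise_sd))
    names(prom_m) <- names(body_m) <- genes$gene_id
    bg_level <- setNames(stats::rbeta(nrow(frag), 8, 2), frag$frag_id)

    n_var <- round(config$variable_cgi_fraction * nrow(annotation$cgis))
    var_cgis <- if (n_var > 0) {
      sort(sample(annotation$cgis$cgi_id, n_var))
    } else character(0)

    expr_truth <- tibble::tibble(gene_id = genes$gene_id, baseline_fpkm = e_g)
    meth_truth <- dplyr::bind_rows(
      tibble::tibble(region_type = "promoter", region_id = genes$gene_id,
                     level = unname(prom_m)),
      tibble::tibble(region_type = "gene_body", region_id = genes$gene_id,
                     level = unname(body_m)),
      tibble::tibble(region_type = "cgi", region_id = annotation$cgis$cgi_id,
                     level = ifelse(annotation$cgis$cgi_id %in% var_cgis, 0.5,
                                    unname(prom_m[annotation$cgis$gene_id]))))
    meth_truth$variable <- meth_truth$region_type == "cgi" &
      meth_truth$region_id %in% var_cgis

    # per-CpG baseline methylation truth
    cpg_m <- dplyr::case_when(
      cpgs$region == "promoter" ~ unname(prom_m[cpgs$gene_id]),
      cpgs$region == "body" ~ unname(body_m[cpgs$gene_id]),
      TRUE ~ unname(bg_level[cpgs$frag_id]))

    # --- RRBS capture, depth, methylation ---------------------------------
    frag$bin_id <- assign_to_bins(frag$chrom, frag$start, bins, "fragment")
    copy_wide <- tidyr::pivot_wider(cnv_truth, names_from = "bin_id",
                                    values_from = "copy")
    copy_mat <- as.matrix(copy_wide[, -1, drop = FALSE])
    rownames(copy_mat) <- copy_wide$cell
    frag_copy <- copy_mat[, frag$bin_id, drop = FALSE]  # cells x fragments

    p_cap <- pmin(config$capture_prob * frag_copy / 2, 1)
    cap <- matrix(runif(length(p_cap)) < p_cap, nrow = nrow(p_cap),
                  dimnames = dimnames(p_cap))

    cap_long <- tibble::tibble(
      cell = rep(rownames(cap), times = ncol(cap)),
      frag_idx = rep(seq_len(ncol(cap)), each = nrow(cap)),
      captured = as.vector(cap))
    cap_long <- dplyr::filter(cap_long, .data$captured)
    cap_long$frag_id <- frag$frag_id[cap_long$frag_idx]
    cap_long$bin_id <- frag$bin_id[cap_long$frag_idx]
    capture_counts <- dplyr::count(cap_long, .data$cell, .data$bin_id,
                                   name = "n_captured")
    capture_counts <- dplyr::left_join(
      tidyr::expand_grid(cell = cells$cell, bin_id = bins$bin_id),
      capture_counts, by = c("cell", "bin_id")) |>
      dplyr::mutate(n_captured = tidyr::replace_na(.data$n_captured, 0L))

    # expand captured fragments to CpGs
    cpg_idx_by_frag <- split(seq_len(nrow(cpgs)), cpgs$frag_id)
    n_cpg_frag <- lengths(cpg_idx_by_frag)[cap_long$frag_id]
    calls <- tibble::tibble(
      cell = rep(cap_long$cell, n_cpg_frag),
      cpg_idx = unlist(cpg_idx_by_frag[cap_long$frag_id], use.names = FALSE))
    depth <- if (config$depth_model == "fixed") {
      rep(round(config$depth_mean), nrow(calls))
    } else if (is.finite(config$overdispersion)) {
      stats::rnbinom(nrow(calls), mu = config$depth_mean,
                     size = config$overdispersion)
    } else {
      rpois(nrow(calls), config$depth_mean)
    }
    keep <- depth > 0 &
      (config$cpg_dropout == 0 | runif(nrow(calls)) >= config$cpg_dropout)
    calls <- calls[keep, ]
    depth <- depth[keep]

    m <- cpg_m[calls$cpg_idx]
    # per-cell bimodal levels for variable CGIs
    if (length(var_cgis) > 0) {
      vc <- which(!is.na(cpgs$cgi_id[calls$cpg_idx]) &
                    cpgs$cgi_id[calls$cpg_idx] %in% var_cgis)
      if (length(vc) > 0) {
        key <- paste(calls$cell[vc], cpgs$cgi_id[calls$cpg_idx[vc]])
        ukey <- unique(key)
        lev <- sample(config$variable_levels, length(ukey), replace = TRUE)
        m[vc] <- lev[match(key, ukey)]
      }
    }
    if (config$meth_copy_coupling != 0) {
      cpg_bin <- assign_to_bins(cpgs$chrom[calls$cpg_idx],
                                cpgs$pos[calls$cpg_idx] - 1L, bins, "CpG")
      cn <- copy_mat[cbind(match(calls$cell, rownames(copy_mat)),
                           match(cpg_bin, colnames(copy_mat)))]
      m <- stats::plogis(stats::qlogis(pmin(pmax(m, 1e-6), 1 - 1e-6)) +
                           config$meth_copy_coupling * (cn - 2))
    }
    if (config$meth_model == "bernoulli") {
      state <- runif(nrow(calls)) < m
      m <- ifelse(state, 1 - config$meth_error, config$meth_error)
    }
    meth <- rbinom(nrow(calls), depth, m)
    calls <- tibble::tibble(cell = calls$cell,
                            chrom = cpgs$chrom[calls$cpg_idx],
                            pos = cpgs$pos[calls$cpg_idx],
                            meth = meth, unmeth = depth - meth)
    calls <- dplyr::arrange(calls, .data$cell, .data$chrom, .data$pos)

    # --- per-bin sequenced-base depth -------------------------------------
    reads_per_frag <- if (config$depth_model == "fixed") {
      rep(round(config$depth_mean), nrow(cap_long))
    } else {
      rpois(nrow(cap_long), config$depth_mean)
    }
    bases <- reads_per_frag * 2 * config$read_len
    bin_depth <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(cell = cap_long$cell,
                                     bin_id = cap_long$bin_id, bases = bases),
                      .data$cell, .data$bin_id),
      depth = sum(.data$bases), .groups = "drop")
    bin_depth <- dplyr::left_join(
      tidyr::expand_grid(cell = cells$cell, bin_id = bins$bin_id),
      bin_depth, by = c("cell", "bin_id")) |>
      dplyr::mutate(depth = tidyr::replace_na(.data$depth, 0))

    # diploid bulk control: expected base coverage per bin
    frag_tab <- dplyr::count(frag, .data$bin_id, name = "n_frag")
    control <- dplyr::left_join(bins[, "bin_id"], frag_tab, by = "bin_id") |>
      dplyr::mutate(depth = tidyr::replace_na(.data$n_frag, 0L) *
                      config$capture_prob * config$depth_mean *
                      2 * config$read_len) |>
      dplyr::select("bin_id", "depth")

    # --- expression -------------------------------------------------------
    genes$bin_id <- assign_to_bins(genes$chrom, genes$tss, bins, "gene")
    gene_copy <- copy_mat[, genes$bin_id, drop = FALSE]  # cells x genes
    mu <- sweep(gene_copy / 2, 2, e_g, `*`)
    fpkm <- if (config$expr_sdlog > 0) {
      matrix(rlnorm(length(mu), meanlog = log(pmax(mu, 1e-12)),
                    sdlog = config$expr_sdlog), nrow = nrow(mu))
    } else mu
    fpkm[mu == 0] <- 0
    if (config$expr_dropout > 0) {
      fpkm[matrix(runif(length(fpkm)) < config$expr_dropout,
                  nrow = nrow(fpkm))] <- 0
    }
    dimnames(fpkm) <- list(rownames(gene_copy), genes$gene_id)
    expression <- tibble::as_tibble(fpkm) |>
      dplyr::mutate(cell = rownames(fpkm), .before = 1) |>
      tidyr::pivot_longer(-"cell", names_to = "gene_id", values_to = "fpkm") |>
      dplyr::arrange(.data$gene_id, .data$cell)
    reference <- tibble::tibble(gene_id = genes$gene_id, fpkm = e_g)

    truth <- structure(list(cells = cells, cnv_truth = cnv_truth,
                            meth_truth = meth_truth, expr_truth = expr_truth,
                            variable_cgis = var_cgis, seed = seed),
                       class = "trio_truth")
    structure(list(truth = truth, calls = calls, bin_depth = bin_depth,
                   capture_counts = capture_counts, expression = expression,
                   reference = reference, control = control,
                   annotation = annotation, config = config),
              class = "trio_sim")
  })
}

#' @export
print.trio_sim <- function(x, ...) {
  cat("<trio_sim> ", nrow(x$truth$cells), " cells (",
      paste(unique(x$truth$cells$subpop), collapse = ", "), "), ",
      nrow(x$calls), " CpG calls, ",
      length(unique(x$expression$gene_id)), " genes\n", sep = "")
  invisible(x)
}

#' Write / read simulator ground truth
#'
#' Plain TSV round-trip of a `trio_truth` object (cells, per-cell per-bin copy
#' number, per-region methylation means, per-gene baseline expression).
#'
#' @param truth a `trio_truth` object from [simulate_population()].
#' @param dir output directory (created if needed).
#' @return `write_truth()` the directory invisibly; `read_truth()` a
#'   `trio_truth` object.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "trio_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(truth$cells, file.path(dir, "cells.tsv"))
  readr::write_tsv(truth$cnv_truth, file.path(dir, "cnv_truth.tsv"))
  readr::write_tsv(truth$meth_truth, file.path(dir, "meth_truth.tsv"))
  readr::write_tsv(truth$expr_truth, file.path(dir, "expr_truth.tsv"))
  writeLines(jsonlite::toJSON(list(seed = truth$seed,
                                   variable_cgis = truth$variable_cgis),
                              auto_unbox = TRUE, digits = NA),
             file.path(dir, "truth_meta.json"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "truth_meta.json"))
  structure(list(
    cells = readr::read_tsv(file.path(dir, "cells.tsv"),
                            show_col_types = FALSE),
    cnv_truth = readr::read_tsv(file.path(dir, "cnv_truth.tsv"),
                                show_col_types = FALSE),
    meth_truth = readr::read_tsv(file.path(dir, "meth_truth.tsv"),
                                 show_col_types = FALSE),
    expr_truth = readr::read_tsv(file.path(dir, "expr_truth.tsv"),
                                 show_col_types = FALSE),
    variable_cgis = as.character(meta$variable_cgis %||% character(0)),
    seed = meta$seed), class = "trio_truth")
}
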