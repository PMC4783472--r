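# Small fixture builders shared across test files.

# Random toy genome as a named character vector (not via the package's
# simulate_genome, so digestion tests stay independent of it).
random_genome <- function(sizes, seed, gc = 0.5) {
  withr::with_seed(seed, {
    setNames(vapply(sizes, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1)), names(sizes))
  })
}

# Minimal call table: one row per site, meth/unmeth given directly.
make_calls <- function(cell, chrom, pos, meth, unmeth) {
  tibble::tibble(cell = cell, chrom = chrom, pos = as.integer(pos),
                 meth = as.integer(meth), unmeth = as.integer(unmeth))
}

# Filtered-style calls with a known level column (bypasses read counts).
make_level_calls <- function(cell, chrom, pos, level) {
  tibble::tibble(cell = cell, chrom = chrom, pos = as.integer(pos),
                 level = level, call = as.integer(level >= 0.5))
}

# A small annotation + simulation pair used by several recovery tests.
small_sim <- function(seed, n_chrom = 4, frags_per_bin = 400,
                      config = NULL) {
  ann <- simulate_annotation(n_chrom = n_chrom, frags_per_bin = frags_per_bin,
                             genes_per_bin = 15, seed = seed)
  cfg <- config %||% sim_config(subpops = list(
    A = list(n_cells = 5, events = list(
      list(chrom = "chr1", start = 0, end = 4e7, copy = 3))),
    B = list(n_cells = 5, events = list(
      list(chrom = "chr2", start = 0, end = 4e7, copy = 1)))))
  list(ann = ann, sim = simulate_population(cfg, ann, seed = seed + 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
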