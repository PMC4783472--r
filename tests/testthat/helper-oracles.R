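# Independent oracles used across the suite. These deliberately use naive
# enumeration / direct formula evaluation, never the package's own code paths.

# Brute-force MspI digestion: scan for every CCGG offset with gregexpr and
# apply the C^CGG cut rule directly.
oracle_digest <- function(seq) {
  hits <- gregexpr("CCGG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1 || length(hits) < 2) {
    return(data.frame(start = integer(), end = integer()))
  }
  cuts <- as.integer(hits)  # 1-based match start == 0-based cut position
  data.frame(start = cuts[-length(cuts)], end = cuts[-1])
}

# Exhaustive multiplicity of a pattern across both C->T collapsed strands.
oracle_occurrences <- function(read, chrom_seqs) {
  revcomp <- function(x) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(x, "")[[1]]),
                                      collapse = ""))
  collapse <- function(x) chartr("C", "T", x)
  subjects <- c(vapply(chrom_seqs, collapse, ""),
                vapply(vapply(chrom_seqs, revcomp, ""), collapse, ""))
  pat <- collapse(read)
  sum(vapply(subjects, function(s) {
    h <- gregexpr(pat, s, fixed = TRUE)[[1]]
    if (h[1] == -1) 0L else length(h)
  }, integer(1)))
}

# Exhaustive Viterbi: enumerate every state path, score it, return the argmax.
# Grids and switch counts are cached per sequence length for speed.
.oracle_grid_cache <- new.env(parent = emptyenv())
oracle_viterbi <- function(x, states, sigma, stay_prob) {
  k <- length(states)
  n <- length(x)
  key <- paste(n, k)
  if (is.null(.oracle_grid_cache[[key]])) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
    switches <- if (n > 1) {
      rowSums(grid[, -1, drop = FALSE] != grid[, -n, drop = FALSE])
    } else rep(0L, nrow(grid))
    .oracle_grid_cache[[key]] <- list(grid = grid, switches = switches)
  }
  cache <- .oracle_grid_cache[[key]]
  emis <- vapply(states, function(s) dnorm(x, s, sigma, log = TRUE),
                 numeric(n))
  emis <- matrix(emis, nrow = n)
  sc <- numeric(nrow(cache$grid))
  for (t in seq_len(n)) sc <- sc + emis[t, cache$grid[, t]]
  if (n > 1) {
    sc <- sc + cache$switches * log((1 - stay_prob) / (k - 1)) +
      (n - 1 - cache$switches) * log(stay_prob)
  }
  states[cache$grid[which.max(sc), ]]
}

# Two-sided Fisher p-value for a 2x2 table by direct hypergeometric
# enumeration (sum of all table probabilities <= that of the observed table).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  kk <- a + c
  xs <- max(0, kk - n):min(kk, m)
  probs <- dhyper(xs, m, n, kk)
  p_obs <- dhyper(a, m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Direct evaluation of the reliability-weighted variance formula.
oracle_weighted_var <- function(x, w) {
  sw <- sum(w)
  m <- sum(w * x) / sw
  sum(w * (x - m)^2) / (sw - sum(w^2) / sw)
}
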