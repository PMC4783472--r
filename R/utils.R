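#' @importFrom rlang %||% abort warn
#' @importFrom stats dnorm pnorm qchisq cor sd var median prcomp cutree hclust
#'   dist fisher.test wilcox.test p.adjust rpois rbinom rnorm rlnorm runif
#'   setNames complete.cases quantile
#' @importFrom utils head tail
#' @importFrom ggplot2 autoplot
#' @import methods
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_trio <- function(...) rlang::abort(paste0(...), class = "trioscope_error")

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    stop_trio(name, " must be a single finite number ",
              if (strict) "greater than " else "not less than ", min)
  }
  invisible(x)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_trio(name, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 means
#' identical partitions, 0 is the expected value for unrelated ones. Used to
#' score recovered cell subpopulations against simulator truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1].
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop_trio("label vectors must have equal length")
  if (length(a) < 2L) stop_trio("need at least 2 items")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# Restore the caller's RNG state after a seeded simulation.
with_preserved_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
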