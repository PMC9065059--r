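#' @useDynLib g4splice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median chisq.test wilcox.test ks.test rbinom runif rnorm
#'   rlnorm hclust cutree dist quantile plogis qlogis setNames
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement over the A/C/G/T/N alphabet.
#'
#' @param x character vector of upper-case nucleotide strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    paste(rev(comp[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Wilson score interval
#'
#' 95\% (by default) binomial confidence interval for x successes out of n.
#'
#' @param x number of successes (vectorised).
#' @param n number of trials.
#' @param z normal quantile, default 1.96.
#' @return data.frame with columns `lower` and `upper`.
#' @export
wilson_ci <- function(x, n, z = 1.96) {
  n <- rep_len(n, length(x))
  p <- ifelse(n > 0, x / n, NA_real_)
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  data.frame(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

stop_ctx <- function(..., ctx = NULL) {
  msg <- paste0(...)
  if (!is.null(ctx)) msg <- paste0(msg, " [", ctx, "]")
  stop(msg, call. = FALSE)
}

# derive a reproducible child seed from a master seed and a small counter,
# kept inside the 32-bit integer range
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1103L + counter * 12347) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
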