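#' Hypergeometric over-representation (upper-tail) probability
#'
#' Computes the probability of observing `x` or more class members in a draw
#' of `N` items taken without replacement from a background of `M` items of
#' which `K` belong to the class:
#' \deqn{p = \sum_{i=x}^{\min(N,K)} \frac{\binom{K}{i}\binom{M-K}{N-i}}{\binom{M}{N}}}
#' The tail is inclusive of `x`, so `x = 0` always gives 1. The sum is
#' accumulated in log space (log binomial coefficients combined by
#' log-sum-exp), so p-values far below double underflow are still available
#' on the log10 scale via `hg_log10_tail()`.
#'
#' @param x observed overlap count, `0 <= x <= min(N, K)`.
#' @param M background capacity (total number of items), `M >= 0`.
#' @param K class capacity (number of class members in the background).
#' @param N draw size (size of the tested set).
#' @return `hg_tail()`: the upper-tail probability in `[0, 1]` (0 on
#'   underflow); `hg_log10_tail()`: the base-10 logarithm of the same
#'   probability, finite even when the probability itself underflows.
#' @examples
#' hg_tail(3, M = 15, K = 4, N = 5)      # 231/3003
#' hg_log10_tail(3, M = 15, K = 4, N = 5)
#' @export
hg_tail <- function(x, M, K, N) {
  p <- exp(hg_log_tail(x, M, K, N))
  min(p, 1)
}

#' @rdname hg_tail
#' @export
hg_log10_tail <- function(x, M, K, N) {
  min(hg_log_tail(x, M, K, N), 0) / log(10)
}

# natural-log upper tail; shared validation lives here
hg_log_tail <- function(x, M, K, N) {
  check_hg_params(x, M, K, N)
  if (x == 0) return(0)
  i <- x:min(N, K)
  lterms <- lchoose(K, i) + lchoose(M - K, N - i) - lchoose(M, N)
  log_sum_exp(lterms)
}

check_hg_params <- function(x, M, K, N) {
  vals <- c(x = x, M = M, K = K, N = N)
  if (length(vals) != 4L || anyNA(vals) || any(vals < 0) ||
      any(vals != round(vals))) {
    stop("hypergeometric parameters must be single non-negative integers",
         call. = FALSE)
  }
  if (K > M) stop("invalid parameters: K > M", call. = FALSE)
  if (N > M) stop("invalid parameters: N > M", call. = FALSE)
  if (x > min(N, K)) {
    stop("invalid parameters: x > min(N, K)", call. = FALSE)
  }
  invisible(TRUE)
}

log_sum_exp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Frequency ratio of a class in a tested set
#'
#' The ratio between the fraction of class members in the tested set and the
#' fraction in the background, `(x/N) / (K/M)`. A descriptive effect-size
#' companion to the enrichment p-value: values above 1 indicate
#' over-representation. Defined as 0 when `x = 0`; callers are expected to
#' skip classes with `K = 0` before testing.
#'
#' @inheritParams hg_tail
#' @return a non-negative number.
#' @export
frequency_ratio <- function(x, N, K, M) {
  if (N <= 0 || M <= 0) {
    stop("frequency ratio requires N > 0 and M > 0", call. = FALSE)
  }
  if (x == 0) return(0)
  (x / N) / (K / M)
}

#' One-tailed Fisher's exact test on the enrichment 2x2 table
#'
#' Builds the contingency table `(x, N - x; K - x, M - K - N + x)` and
#' returns the one-tailed ("greater") exact p-value via
#' [stats::fisher.test()]. Mathematically identical to [hg_tail()]; it is
#' kept as an independent cross-check of the log-space tail computation and
#' is used as an oracle by the test suite.
#'
#' @inheritParams hg_tail
#' @return the one-tailed exact p-value.
#' @export
fisher_one_tailed <- function(x, M, K, N) {
  check_hg_params(x, M, K, N)
  tab <- matrix(c(x, K - x, N - x, M - K - N + x), nrow = 2)
  if (any(tab < 0)) {
    stop("invalid parameters: negative cell in 2x2 table", call. = FALSE)
  }
  stats::fisher.test(tab, alternative = "greater")$p.value
}
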