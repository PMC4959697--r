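#' Adjust a family of p-values for multiple testing
#'
#' Applies the Benjamini-Hochberg step-up false-discovery-rate procedure
#' (default) or the Bonferroni correction to a family of nominal p-values.
#' The adjusted value of each test is its q-value: under BH, declaring all
#' tests with `q <= alpha` significant controls the FDR at `alpha`.
#'
#' The family is composed by the calling analysis: both position and
#' connection analyses correct jointly over every (group, class) or
#' (group, class-pair) combination tested in one invocation.
#'
#' BH computes `q_(i) = min_(j >= i) p_(j) * n / j` over the ascending order
#' statistics, capped at 1, and maps the values back to input order; ties are
#' handled naturally by the running minimum. Bonferroni is `min(p * n, 1)`.
#'
#' @param p numeric vector of nominal p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.005, 0.5))                 # 0.01 0.50
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04))     # all 0.04
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value family", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p)
  if (method == "bonferroni") return(pmin(p * n, 1))
  # BH step-up: work from the largest p downwards with a running minimum
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n / (n:1) * p[o]))
  q[ro]
}
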