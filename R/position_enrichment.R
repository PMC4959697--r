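#' Position group enrichment analysis
#'
#' Tests every (group, class) combination for over-representation of the
#' class inside the group with the hypergeometric upper-tail test. For a
#' group A of size N and a class with capacity K inside the background of
#' size M, the observed overlap x = |A intersect B| is scored by
#' P(X >= x) under random sampling of N positions without replacement.
#' All (group, class) p-values from one invocation form a single
#' multiple-testing family.
#'
#' Overlapping classes are allowed and tested independently (the usual
#' convention for categorical over-representation analysis); classes empty
#' in the background are skipped with a message.
#'
#' @param groups a [position_groups()] object.
#' @param annotation a [neuro_annotation()].
#' @param space the background [position_space()].
#' @param correction `"BH"` (false discovery rate, default) or
#'   `"bonferroni"`.
#' @param alpha significance level applied to adjusted p-values.
#' @return a data frame of class `enrichment_result`, one row per tested
#'   combination, with columns `group`, `class`, `x`, `N`, `K`, `M`, `p`,
#'   `log10_p` (exact even when `p` underflows to 0), `q`,
#'   `frequency_ratio`, `test` (`"HG"`) and `significant`.
#' @examples
#' sp <- position_space(1:20)
#' grp <- position_groups(list(roi = 1:8))
#' ann <- neuro_annotation(list(VN = c(1:4, 15), AN = 9:12))
#' run_position_analysis(grp, ann, sp)
#' @export
run_position_analysis <- function(groups, annotation, space,
                                  correction = c("BH", "bonferroni"),
                                  alpha = 0.05) {
  correction <- match.arg(correction)
  stopifnot(inherits(groups, "position_groups"),
            inherits(annotation, "neuro_annotation"),
            inherits(space, "position_space"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  for (g in names(groups$groups)) {
    check_ids_in_space(groups$groups[[g]], space, paste0("group '", g, "'"))
  }
  ann <- restrict_annotation(annotation, space)
  classes <- ann$classes
  M <- space$M

  rows <- list()
  for (g in names(groups$groups)) {
    A <- groups$groups[[g]]
    N <- length(A)
    for (cl in names(classes)) {
      B <- classes[[cl]]
      K <- length(B)
      x <- sum(A %in% B)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, class = cl, x = x, N = N, K = K, M = M,
        p = hg_tail(x, M, K, N),
        log10_p = hg_log10_tail(x, M, K, N),
        frequency_ratio = frequency_ratio(x, N, K, M),
        test = "HG", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- adjust_pvalues(res$p, correction)
  res$significant <- res$q <= alpha
  res <- res[, c("group", "class", "x", "N", "K", "M", "p", "log10_p", "q",
                 "frequency_ratio", "test", "significant")]
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "correction") <- correction
  attr(res, "alpha") <- alpha
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment results:", nrow(x), "tested combination(s), ",
      sum(x$significant), "significant at alpha =", attr(x, "alpha"),
      "(", attr(x, "correction"), "corrected )\n")
  print.data.frame(x[order(x$q, x$p), ], digits = 4, row.names = FALSE)
  invisible(x)
}
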