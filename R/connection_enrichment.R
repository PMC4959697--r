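# Connection group enrichment: parametric hypergeometric test over class
# pairs and the non-parametric degree-preserving permutation (DPP) test.

#' DPP test configuration
#'
#' @param m number of randomized graphs drawn for the empirical null
#'   (default 1000; the smallest attainable p-value is `1/m`).
#' @param swaps_per_edge successful double-edge swaps per randomized graph,
#'   as a multiple of the edge count (default 10, the usual Maslov-Sneppen
#'   burn-in).
#' @param seed integer seed; every sample is seeded deterministically from
#'   `(seed, stream, sample index)` so runs are reproducible and samples
#'   order-independent.
#' @return a `dpp_config` list.
#' @export
dpp_config <- function(m = 1000L, swaps_per_edge = 10, seed = 1L) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("dpp m must be >= 1", call. = FALSE)
  if (swaps_per_edge < 1) stop("swaps_per_edge must be >= 1", call. = FALSE)
  structure(list(m = m, swaps_per_edge = swaps_per_edge,
                 seed = as.integer(seed)),
            class = "dpp_config")
}

#' Capacity of a class pair
#'
#' Number of possible unordered connections between annotation classes C
#' and D: `|C| * |D|` for disjoint classes, `|C| * (|C| - 1) / 2` for the
#' intra-class case C = D.
#'
#' @param nC,nD class sizes.
#' @param same logical, is this the intra-class case?
#' @return the pair capacity K.
#' @export
class_pair_capacity <- function(nC, nD, same = FALSE) {
  if (same) nC * (nC - 1) / 2 else nC * nD
}

# logical index of edges joining C and D (both endpoints in C when C == D)
edge_in_class_pair <- function(edges, C, D) {
  inC1 <- edges[, 1L] %in% C
  inC2 <- edges[, 2L] %in% C
  if (identical(sort(C), sort(D))) return(inC1 & inC2)
  inD1 <- edges[, 1L] %in% D
  inD2 <- edges[, 2L] %in% D
  (inC1 & inD2) | (inD1 & inC2)
}

#' Count connections between two annotation classes
#'
#' The observed statistic a(A, C, D): the number of edges of a connection
#' group with one endpoint in class C and the other in class D (both
#' endpoints in C for the intra-class case). C and D must be disjoint
#' unless identical.
#'
#' @param edges two-column edge matrix (one unordered pair per row).
#' @param C,D integer vectors of position ids.
#' @return the edge count.
#' @export
count_class_pair_edges <- function(edges, C, D) {
  same <- identical(sort(unique(C)), sort(unique(D)))
  if (!same && length(intersect(C, D)) > 0L) {
    stop("annotation classes must be disjoint for connection analysis",
         call. = FALSE)
  }
  sum(edge_in_class_pair(edges, C, D))
}

#' Parametric (hypergeometric) connection enrichment test
#'
#' Tests whether a connection group contains more C-D edges than expected
#' when its N edges are drawn uniformly from all `M = |S|(|S|-1)/2`
#' possible position pairs. This null ignores the degree distribution of
#' the observed graph; see [dpp_test()] for the degree-aware alternative.
#'
#' @param edges two-column edge matrix of the connection group.
#' @param C,D integer vectors of position ids (disjoint, or identical for
#'   an intra-class test).
#' @param space the background [position_space()].
#' @return list with `x`, `N`, `K`, `M`, `p`, `log10_p`, `frequency_ratio`.
#' @export
hg_connection_test <- function(edges, C, D, space) {
  stopifnot(inherits(space, "position_space"))
  if (space$M < 2L) stop("need at least two background positions",
                         call. = FALSE)
  same <- identical(sort(unique(C)), sort(unique(D)))
  M <- space$M * (space$M - 1) / 2
  K <- class_pair_capacity(length(unique(C)), length(unique(D)), same)
  N <- nrow(edges)
  x <- count_class_pair_edges(edges, C, D)
  list(x = x, N = N, K = K, M = M,
       p = hg_tail(x, M, K, N),
       log10_p = hg_log10_tail(x, M, K, N),
       frequency_ratio = frequency_ratio(x, N, K, M))
}

#' Draw one degree-preserving randomization of a graph
#'
#' Produces a uniform-ish sample from the set of simple graphs with the
#' same degree sequence as the input, via a chain of successful double-edge
#' swaps (two disjoint edges are replaced by two others on the same four
#' nodes; proposals creating self-loops or duplicate edges are rejected).
#' Graphs admitting no valid swap (e.g. stars) are returned unchanged with
#' a "frozen graph" warning.
#'
#' @param edges two-column edge matrix.
#' @param config a [dpp_config()].
#' @param sample_index index of the sample within the chain family;
#'   different indices give independent samples under the same seed.
#' @return a two-column edge matrix with the same degree sequence.
#' @export
dpp_sample <- function(edges, config = dpp_config(), sample_index = 1L) {
  edges <- normalize_pairs(edges)
  res <- cpp_swap_chain(edges, n_swaps = config$swaps_per_edge * nrow(edges),
                        seed = config$seed, stream = 0, index = sample_index)
  if (res$successes < res$target) {
    warning("frozen graph: only ", res$successes, " of ", res$target,
            " swaps possible; returning partially randomized graph",
            call. = FALSE)
  }
  colnames(res$edges) <- c("i", "j")
  res$edges
}

#' Degree-preserving permutation (DPP) connection enrichment test
#'
#' Empirical over-representation test under the null that the observed
#' graph was drawn uniformly from all simple graphs with the same node
#' degrees. `m` randomized graphs are generated (each an independent swap
#' chain from the observed graph) and scored by their C-D edge count; the
#' empirical p-value is the fraction of scores greater than or equal to the
#' observed count, floored at `1/m` (the smallest significance the sample
#' size can support).
#'
#' @inheritParams hg_connection_test
#' @param config a [dpp_config()].
#' @param stream integer stream id separating RNG streams of different
#'   (group, class-pair) tests run under one seed.
#' @return list with `x` (observed), `N`, `K`, `M`, `p`, `scores` (the m
#'   null scores) and `frequency_ratio`.
#' @export
dpp_test <- function(edges, C, D, space, config = dpp_config(),
                     stream = 1L) {
  stopifnot(inherits(space, "position_space"))
  same <- identical(sort(unique(C)), sort(unique(D)))
  if (!same && length(intersect(C, D)) > 0L) {
    stop("annotation classes must be disjoint for connection analysis",
         call. = FALSE)
  }
  edges <- normalize_pairs(edges)
  x <- count_class_pair_edges(edges, C, D)
  n_nodes <- max(space$ids, edges)
  in_c <- in_d <- integer(n_nodes)
  in_c[unique(C)] <- 1L
  if (!same) in_d[unique(D)] <- 1L
  res <- cpp_dpp_scores(edges, in_c, in_d, same, config$m,
                        n_swaps = config$swaps_per_edge * nrow(edges),
                        seed = config$seed, stream = stream)
  if (res$min_successes < res$target && nrow(edges) > 1L) {
    warning("frozen graph: some DPP samples achieved only ",
            res$min_successes, " of ", res$target, " swaps", call. = FALSE)
  }
  M <- space$M * (space$M - 1) / 2
  K <- class_pair_capacity(length(unique(C)), length(unique(D)), same)
  p <- max(sum(res$scores >= x), 1L) / config$m
  list(x = x, N = nrow(edges), K = K, M = M, p = p, scores = res$scores,
       frequency_ratio = frequency_ratio(x, nrow(edges), K, M))
}

#' Connection group enrichment analysis
#'
#' Runs the parametric hypergeometric test and/or the degree-preserving
#' permutation test for every connection group against every unordered
#' annotation class pair (including intra-class pairs) with nonzero
#' capacity. P-values are corrected jointly across all combinations,
#' separately per test type, and the class-pair label is `"C-D"` (or
#' `"C-C"` for intra-class results).
#'
#' Annotation classes must be pairwise disjoint over the background: the
#' pair capacities and edge counting presuppose a (partial) partition.
#'
#' @param groups a [connection_groups()] object.
#' @param annotation a [neuro_annotation()] with pairwise-disjoint classes.
#' @param space the background [position_space()].
#' @param tests character subset of `c("HG", "DPP")`.
#' @param correction `"BH"` or `"bonferroni"`.
#' @param alpha significance level on adjusted p-values.
#' @param config a [dpp_config()] (used when `"DPP"` is requested).
#' @return an `enrichment_result` data frame; DPP rows carry `log10_p =
#'   log10(p)` of the empirical p-value.
#' @export
run_connection_analysis <- function(groups, annotation, space,
                                    tests = c("HG", "DPP"),
                                    correction = c("BH", "bonferroni"),
                                    alpha = 0.05,
                                    config = dpp_config()) {
  correction <- match.arg(correction)
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(inherits(groups, "connection_groups"),
            inherits(annotation, "neuro_annotation"),
            inherits(space, "position_space"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  for (g in names(groups$groups)) {
    check_ids_in_space(c(groups$groups[[g]]), space,
                       paste0("group '", g, "'"))
  }
  ann <- restrict_annotation(annotation, space)
  classes <- ann$classes
  all_ids <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("annotation classes must be disjoint for connection analysis",
         call. = FALSE)
  }
  cn <- names(classes)
  pairs <- expand.grid(a = seq_along(cn), b = seq_along(cn))
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  M <- space$M * (space$M - 1) / 2

  rows <- list()
  stream <- 0L
  for (g in names(groups$groups)) {
    edges <- groups$groups[[g]]
    N <- nrow(edges)
    for (r in seq_len(nrow(pairs))) {
      ca <- cn[pairs$a[r]]; cb <- cn[pairs$b[r]]
      same <- ca == cb
      K <- class_pair_capacity(length(classes[[ca]]), length(classes[[cb]]),
                               same)
      stream <- stream + 1L
      if (K == 0) {
        message("skipping zero-capacity class pair ", ca, "-", cb)
        next
      }
      x <- count_class_pair_edges(edges, classes[[ca]], classes[[cb]])
      ratio <- frequency_ratio(x, N, K, M)
      label <- paste(ca, cb, sep = "-")
      if ("HG" %in% tests) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, class = label, x = x, N = N, K = K, M = M,
          p = hg_tail(x, M, K, N), log10_p = hg_log10_tail(x, M, K, N),
          frequency_ratio = ratio, test = "HG", stringsAsFactors = FALSE)
      }
      if ("DPP" %in% tests) {
        d <- dpp_test(edges, classes[[ca]], classes[[cb]], space, config,
                      stream = stream)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, class = label, x = x, N = N, K = K, M = M,
          p = d$p, log10_p = log10(d$p),
          frequency_ratio = ratio, test = "DPP", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) stop("no usable class pairs", call. = FALSE)
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (tt in unique(res$test)) {
    sel <- res$test == tt
    res$q[sel] <- adjust_pvalues(res$p[sel], correction)
  }
  res$significant <- res$q <= alpha
  res <- res[, c("group", "class", "x", "N", "K", "M", "p", "log10_p", "q",
                 "frequency_ratio", "test", "significant")]
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "correction") <- correction
  attr(res, "alpha") <- alpha
  res
}
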