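# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the tail probability is obtained by explicit
# subset enumeration, and the degree-preserving null space by exhaustive
# graph enumeration.

# P(X >= x) by enumerating all C(M, N) draws from a background whose first
# K items are class members. Only feasible for small M.
enum_hg_tail <- function(x, M, K, N) {
  if (N == 0L) return(as.numeric(x == 0L))
  draws <- utils::combn(M, N)
  mean(colSums(draws <= K) >= x)
}

# all simple graphs on nodes 1..n with exactly `n_edges` edges and the given
# degree sequence; returns a list of 2-column edge matrices
enum_degree_graphs <- function(n, degrees) {
  all_pairs <- utils::combn(n, 2)
  n_edges <- sum(degrees) / 2
  sets <- utils::combn(ncol(all_pairs), n_edges)
  out <- list()
  for (s in seq_len(ncol(sets))) {
    e <- t(all_pairs[, sets[, s], drop = FALSE])
    if (identical(tabulate(c(e), n), as.integer(degrees))) {
      out[[length(out) + 1L]] <- e
    }
  }
  out
}

graph_degrees <- function(edges, n) tabulate(c(edges), nbins = n)

edge_key_set <- function(edges) {
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  sort(paste(lo, hi))
}

is_simple_graph <- function(edges) {
  !any(edges[, 1L] == edges[, 2L]) && !anyDuplicated(edge_key_set(edges))
}
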