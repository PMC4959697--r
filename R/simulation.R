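# Simulation harness: power-law random graphs with implanted noisy
# bicliques, used to validate calibration and power of the HG and DPP
# connection tests and to contrast their null models.

# run expr under a temporary RNG state seeded with `seed` (NULL = leave the
# global stream alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a scale-free random graph by weighted edge sampling
#'
#' Chung-Lu-style generator: node i gets attachment weight
#' `w_i = i^(-1/(exponent-1))`, and edges are drawn by repeatedly sampling
#' endpoint pairs with probability proportional to `w_i * w_j`, rejecting
#' self-loops and duplicates, until `n_edges` distinct edges exist. The
#' resulting degree distribution is approximately power-law with the
#' requested exponent; smaller exponents give heavier tails (a few hubs
#' carrying a large share of the edges), which is the regime where the HG
#' and DPP nulls disagree.
#'
#' @param n_nodes number of nodes (ids `1..n_nodes`).
#' @param n_edges number of distinct edges; must not exceed
#'   `n_nodes * (n_nodes - 1) / 2` (a saturated graph returns the complete
#'   graph).
#' @param exponent target power-law exponent (> 1); 2 and 3 are the usual
#'   comparison points.
#' @param seed optional seed; the same seed always yields the same edge set.
#' @return a two-column edge matrix.
#' @export
sample_power_law_graph <- function(n_nodes, n_edges, exponent = 2,
                                   seed = NULL) {
  stopifnot(n_nodes >= 2, exponent > 1)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    stop("cannot place ", n_edges, " distinct edges on ", n_nodes, " nodes",
         call. = FALSE)
  }
  with_seed(seed, {
    w <- (seq_len(n_nodes))^(-1 / (exponent - 1))
    keys <- integer(0)
    batch <- max(n_edges, 256L)
    tries <- 0L
    max_tries <- 2000L
    while (length(keys) < n_edges && tries < max_tries) {
      tries <- tries + 1L
      u <- sample.int(n_nodes, batch, replace = TRUE, prob = w)
      v <- sample.int(n_nodes, batch, replace = TRUE, prob = w)
      ok <- u != v
      lo <- pmin(u[ok], v[ok]); hi <- pmax(u[ok], v[ok])
      keys <- unique(c(keys, (lo - 1) * n_nodes + hi))
    }
    if (length(keys) < n_edges) {
      stop("edge sampling saturated before reaching ", n_edges, " edges",
           call. = FALSE)
    }
    keys <- keys[seq_len(n_edges)]
    cbind(i = (keys - 1) %/% n_nodes + 1, j = (keys - 1) %% n_nodes + 1)
  })
}

#' Implant a noisy biclique into a graph
#'
#' Adds all `|A| * |B|` edges between two disjoint node sets, then removes
#' each implanted edge independently with probability `noise_q`. Edges of
#' the base graph are never removed, so the result always contains the
#' original edge set; at `noise_q = 1` the graph is returned unchanged
#' (up to edges that already coincided with the implant).
#'
#' @param edges two-column edge matrix of the base graph.
#' @param A,B disjoint integer node sets (rows and columns of the
#'   biclique).
#' @param noise_q per-edge removal probability in `[0, 1]`.
#' @param seed optional seed.
#' @return a two-column edge matrix.
#' @export
implant_biclique <- function(edges, A, B, noise_q = 0, seed = NULL) {
  if (length(intersect(A, B)) > 0L) {
    stop("biclique node sets must be disjoint", call. = FALSE)
  }
  stopifnot(noise_q >= 0, noise_q <= 1)
  with_seed(seed, {
    implant <- as.matrix(expand.grid(i = A, j = B))
    keep <- stats::runif(nrow(implant)) >= noise_q
    implant <- implant[keep, , drop = FALSE]
    if (nrow(implant) == 0L) return(normalize_pairs(edges))
    suppressWarnings(normalize_pairs(rbind(edges, implant)))
  })
}

#' Simulation experiment configuration
#'
#' Defaults mirror the validation design used for the method: graphs with
#' 244 nodes and 363 edges wired with a power-law scheme (exponent 2), a
#' complete 5x5 biclique implanted and degraded by edge-removal noise, and
#' both tests scored against the real implanted pair and a dummy pair.
#'
#' @param n_nodes,n_edges base graph size (defaults 244 and 363; 1000
#'   edges reproduces the high-degree-dummy design).
#' @param exponent power-law exponent (2 or 3).
#' @param implant_size rows/cols of the implanted biclique (default 5).
#' @param noise_q vector of edge-removal probabilities to sweep.
#' @param reps repetitions per noise level (default 100 for test runs; the
#'   full design used 1000).
#' @param dummy_mode `"random"` (fresh random disjoint 5+5 nodes each rep)
#'   or `"high_degree"` (the highest-degree nodes outside the implant,
#'   the adversarial case separating HG from DPP).
#' @param tests subset of `c("HG", "DPP")`.
#' @param dpp a [dpp_config()] for DPP scoring.
#' @param seed master seed; per-rep seeds are derived deterministically.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_nodes = 244L, n_edges = 363L, exponent = 2,
                       implant_size = 5L,
                       noise_q = c(0, 0.25, 0.5, 0.75, 1),
                       reps = 100L, dummy_mode = c("random", "high_degree"),
                       tests = c("HG", "DPP"), dpp = dpp_config(),
                       seed = 1L) {
  dummy_mode <- match.arg(dummy_mode)
  tests <- match.arg(tests, several.ok = TRUE)
  stopifnot(reps >= 1, all(noise_q >= 0 & noise_q <= 1),
            4L * implant_size <= n_nodes)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_edges = as.integer(n_edges), exponent = exponent,
                 implant_size = as.integer(implant_size), noise_q = noise_q,
                 reps = as.integer(reps), dummy_mode = dummy_mode,
                 tests = tests, dpp = dpp, seed = as.integer(seed)),
            class = "sim_config")
}

#' Run the implanted-biclique power experiment
#'
#' Per repetition and noise level: sample a base power-law graph, pick a
#' random disjoint pair of implant sets (A, B) and a dummy pair (A', B')
#' (random, or the highest-degree non-implant nodes), implant the noisy
#' biclique on A-B, then score both class pairs with the requested tests.
#' The real pair measures power; the dummy pair measures specificity, and
#' in the high-degree mode exposes the hypergeometric null's blindness to
#' hub degrees.
#'
#' @param config a [sim_config()].
#' @return data frame with one row per (rep, noise level, test, target):
#'   columns `rep`, `noise_q`, `test`, `target` (`"real"`/`"dummy"`), `x`,
#'   `p`, `log10_p`.
#' @export
run_implant_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$implant_size
  space <- position_space(seq_len(config$n_nodes))
  rows <- vector("list", 0L)
  rid <- 0L
  for (q in config$noise_q) {
    for (r in seq_len(config$reps)) {
      rid <- rid + 1L
      seed_r <- config$seed + 7919L * rid
      base <- sample_power_law_graph(config$n_nodes, config$n_edges,
                                     config$exponent, seed = seed_r)
      sets <- with_seed(seed_r + 1L,
                        sample.int(config$n_nodes, 2L * k))
      A <- sets[seq_len(k)]
      B <- sets[k + seq_len(k)]
      g <- implant_biclique(base, A, B, noise_q = q, seed = seed_r + 2L)
      if (config$dummy_mode == "random") {
        pool <- setdiff(seq_len(config$n_nodes), c(A, B))
        dum <- with_seed(seed_r + 3L, sample(pool, 2L * k))
      } else {
        deg <- tabulate(c(g), nbins = config$n_nodes)
        pool <- setdiff(order(deg, decreasing = TRUE), c(A, B))
        dum <- pool[seq_len(2L * k)]
      }
      Ad <- dum[seq_len(k)]
      Bd <- dum[k + seq_len(k)]
      targets <- list(real = list(A, B), dummy = list(Ad, Bd))
      for (tn in names(targets)) {
        C <- targets[[tn]][[1L]]
        D <- targets[[tn]][[2L]]
        if ("HG" %in% config$tests) {
          h <- hg_connection_test(g, C, D, space)
          rows[[length(rows) + 1L]] <- data.frame(
            rep = rid, noise_q = q, test = "HG", target = tn, x = h$x,
            p = h$p, log10_p = h$log10_p, stringsAsFactors = FALSE)
        }
        if ("DPP" %in% config$tests) {
          cfg <- dpp_config(m = config$dpp$m,
                            swaps_per_edge = config$dpp$swaps_per_edge,
                            seed = config$dpp$seed + seed_r)
          d <- dpp_test(g, C, D, space, cfg,
                        stream = if (tn == "real") 1L else 2L)
          rows[[length(rows) + 1L]] <- data.frame(
            rep = rid, noise_q = q, test = "DPP", target = tn, x = d$x,
            p = d$p, log10_p = log10(d$p), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize an implant experiment
#'
#' Mean and standard deviation of `-log10 p` per (noise level, test,
#' target), the quantities plotted in power-vs-noise curves.
#'
#' @param per_rep output of [run_implant_experiment()].
#' @return data frame with columns `noise_q`, `test`, `target`,
#'   `mean_neg_log10_p`, `sd_neg_log10_p`, `reps`.
#' @export
summarize_implant_experiment <- function(per_rep) {
  stopifnot(is.data.frame(per_rep))
  agg <- stats::aggregate(
    list(mean_neg_log10_p = -per_rep$log10_p),
    by = per_rep[, c("noise_q", "test", "target")], FUN = mean)
  sds <- stats::aggregate(
    list(sd_neg_log10_p = -per_rep$log10_p),
    by = per_rep[, c("noise_q", "test", "target")], FUN = stats::sd)
  ns <- stats::aggregate(
    list(reps = per_rep$log10_p),
    by = per_rep[, c("noise_q", "test", "target")], FUN = length)
  out <- merge(merge(agg, sds), ns)
  out[order(out$test, out$target, out$noise_q), , drop = FALSE]
}
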