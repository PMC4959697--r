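# Connection enrichment: class-pair counting, the parametric HG test, the
# degree-preserving permutation engine and the combined analysis.

test_that("class-pair edge counting follows the definition", {
  e <- rbind(c(1, 3), c(2, 4), c(5, 6))
  expect_equal(count_class_pair_edges(e, C = 1:2, D = 3:4), 2L)
  e2 <- rbind(c(1, 2), c(2, 3), c(1, 9))
  expect_equal(count_class_pair_edges(e2, C = 1:3, D = 1:3), 2L)
  expect_equal(count_class_pair_edges(e, C = 7:8, D = 9:10), 0L)
  expect_error(count_class_pair_edges(e, C = 1:3, D = 3:5), "disjoint")
})

test_that("pair capacities: |C||D| inter-class, C(|C|,2) intra-class", {
  expect_equal(class_pair_capacity(4, 7), 28)
  expect_equal(class_pair_capacity(5, 5, same = TRUE), 10)
  expect_equal(class_pair_capacity(1, 1, same = TRUE), 0)
})

test_that("hg_connection_test matches the enumeration oracle", {
  # |S| = 6 -> M = 15 pair slots, K = 4, N = 5 edges of which x = 3 join C-D
  sp <- position_space(1:6)
  edges <- rbind(c(1, 3), c(1, 4), c(2, 3), c(5, 6), c(2, 5))
  r <- hg_connection_test(edges, C = 1:2, D = 3:4, sp)
  expect_equal(r$x, 3L)
  expect_equal(r$K, 4)
  expect_equal(r$p, 231 / 3003, tolerance = 1e-12)
  expect_equal(r$p, enum_hg_tail(3, 15, 4, 5), tolerance = 1e-12)
  # x = 0 -> p = 1
  r0 <- hg_connection_test(rbind(c(5, 6)), C = 1:2, D = 3:4, sp)
  expect_identical(r0$p, 1)
})

test_that("dpp_sample preserves degrees, edge count and simplicity", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(15:40, 1)
    g <- sample_power_law_graph(n, sample(10:60, 1), runif(1, 1.5, 3))
    r <- dpp_sample(g, dpp_config(seed = i), sample_index = i)
    expect_equal(graph_degrees(r, n), graph_degrees(g, n))
    expect_equal(nrow(r), nrow(g))
    expect_true(is_simple_graph(r))
  }
})

test_that("a star graph is frozen: returned unchanged with a warning", {
  star <- cbind(1L, 2:6)
  expect_warning(r <- dpp_sample(star, dpp_config(seed = 2)), "frozen")
  expect_equal(edge_key_set(r), edge_key_set(star))
})

test_that("4-cycle samples stay inside the enumerated degree-preserving set", {
  cyc <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))
  null_set <- enum_degree_graphs(4, c(2, 2, 2, 2))
  expect_length(null_set, 3L)   # the three labelled 4-cycles
  keys <- vapply(null_set, function(g) paste(edge_key_set(g), collapse = ";"),
                 character(1))
  for (i in 1:25) {
    r <- dpp_sample(cyc, dpp_config(seed = 7), sample_index = i)
    expect_true(paste(edge_key_set(r), collapse = ";") %in% keys)
  }
})

test_that("dpp_test p converges to the enumerated exact value on the 4-cycle", {
  # observed cycle 1-3-2-4 contains edge (1,3); C = {1}, D = {3}.
  # Oracle: of the 3 graphs with degrees (2,2,2,2), 2 contain edge (1,3),
  # so the exact p is 2/3. (Enumerated here, not assumed.)
  null_set <- enum_degree_graphs(4, c(2, 2, 2, 2))
  exact <- mean(vapply(null_set, function(g)
    any(g[, 1] == 1 & g[, 2] == 3), logical(1)))
  expect_equal(exact, 2 / 3)
  cyc <- rbind(c(1, 3), c(2, 3), c(2, 4), c(1, 4))
  m <- 4000L
  d <- dpp_test(cyc, C = 1L, D = 3L, position_space(1:4),
                dpp_config(m = m, seed = 77))
  se <- sqrt(exact * (1 - exact) / m)
  expect_lt(abs(d$p - exact), 3 * se)
})

test_that("dpp_test floors the empirical p at 1/m", {
  # planted complete biclique: the observed C-D count exceeds every
  # degree-preserving randomization, so p must be exactly 1/m
  base <- sample_power_law_graph(100, 150, 2, seed = 3)
  g <- implant_biclique(base, A = 1:5, B = 6:10, noise_q = 0, seed = 4)
  d <- dpp_test(g, C = 1:5, D = 6:10, position_space(1:100),
                dpp_config(m = 500, seed = 5))
  expect_equal(sum(d$scores >= d$x), 0L)
  expect_identical(d$p, 1 / 500)
  # frozen star: every sample equals the observed graph -> p = 1
  star <- cbind(1L, 2:6)
  expect_warning(
    ds <- dpp_test(star, C = 1L, D = 2L, position_space(1:6),
                   dpp_config(m = 50, seed = 6)),
    "frozen")
  expect_identical(ds$p, 1)
})

test_that("dpp p-values live on the grid {1/m, ..., 1} and are reproducible", {
  g <- sample_power_law_graph(60, 90, 2, seed = 8)
  sp <- position_space(1:60)
  cfg <- dpp_config(m = 40, seed = 9)
  d1 <- dpp_test(g, C = 1:6, D = 7:12, sp, cfg)
  d2 <- dpp_test(g, C = 1:6, D = 7:12, sp, cfg)
  expect_identical(d1$p, d2$p)
  expect_identical(d1$scores, d2$scores)
  expect_true(d1$p %in% (seq_len(40) / 40))
})

test_that("run_connection_analysis tests all C(k,2)+k class pairs jointly", {
  syn <- synthetic_connectome()
  res <- run_connection_analysis(syn$groups, syn$annotation, syn$space,
                                 tests = "HG")
  expect_equal(nrow(res), choose(5, 2) + 5L)   # 15 pairs, one group
  expect_equal(res$q, adjust_pvalues(res$p, "BH"))
  expect_equal(unique(res$N), 363L)
  expect_equal(unique(res$M), 1024 * 1023 / 2)
  # planted counts recovered exactly
  for (p in syn$planted) {
    lbl1 <- paste(p[1], p[2], sep = "-"); lbl2 <- paste(p[2], p[1], sep = "-")
    row <- res[res$class %in% c(lbl1, lbl2), ]
    expect_equal(row$x, as.integer(p[3]), label = lbl1)
  }
})

test_that("overlapping classes are rejected for connection analysis", {
  sp <- position_space(1:20)
  cg <- connection_groups(list(g = rbind(c(1, 5), c(2, 6))))
  ann <- neuro_annotation(list(a = 1:5, b = 4:8))
  expect_error(run_connection_analysis(cg, ann, sp), "disjoint")
})

test_that("HG and DPP agree on near-uniform-degree random graphs", {
  # when degrees are exchangeable the two nulls coincide asymptotically;
  # check the paired mean difference over 100 simulated tests
  set.seed(55)
  diffs <- replicate(100, {
    g <- matrix(sample(30, 2 * 45, replace = TRUE), ncol = 2)
    g <- g[g[, 1] != g[, 2], , drop = FALSE]
    g <- suppressWarnings(unique(neuroenrich:::normalize_pairs(g)))
    sp <- position_space(1:30)
    C <- sample(30, 5); D <- sample(setdiff(1:30, C), 5)
    hg <- hg_connection_test(g, C, D, sp)
    dp <- dpp_test(g, C, D, sp, dpp_config(m = 200, seed = sample(1e6, 1)))
    dp$p - hg$p
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.03)
})

test_that("HG and DPP dissociate with hub-concentrated classes", {
  # (a) C, D sit on hubs: their edges are explained by degree alone, so
  #     HG calls enrichment and DPP does not;
  # (b) C, D have low degree spent almost entirely on each other: DPP is
  #     the more significant test.
  sp <- position_space(1:20)
  C <- 1:3; D <- 4:6
  cd <- as.matrix(expand.grid(C, D))[c(1:7), ]
  hubs <- rbind(as.matrix(expand.grid(1:3, 7:14)),
                as.matrix(expand.grid(4:6, 15:20)))
  ga <- suppressWarnings(neuroenrich:::normalize_pairs(rbind(cd, hubs)))
  ha <- hg_connection_test(ga, C, D, sp)
  da <- dpp_test(ga, C, D, sp, dpp_config(m = 400, seed = 10))
  expect_lt(ha$p, 0.01)
  expect_gt(da$p, 0.1)
  expect_lt(ha$p, da$p)

  rest <- t(utils::combn(7:20, 2))
  gb <- suppressWarnings(neuroenrich:::normalize_pairs(rbind(cd, rest)))
  hb <- hg_connection_test(gb, C, D, sp)
  db <- dpp_test(gb, C, D, sp, dpp_config(m = 400, seed = 11))
  expect_lt(db$p, hb$p)
})

test_that("DPP config validation", {
  expect_error(dpp_config(m = 0), "m must be")
  expect_error(dpp_config(swaps_per_edge = 0.5), "swaps_per_edge")
})
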