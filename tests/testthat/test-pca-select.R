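test_that("eigenvector scores honour symmetry on canonical graphs", {
  g <- star_graph(4)
  sc <- eigenvector_scores(g)
  expect_gt(sc["c0"], max(sc[paste0("l0", 1:4)]))
  expect_equal(unname(diff(range(sc[paste0("l0", 1:4)]))), 0, tolerance = 1e-12)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(unname(eigenvector_scores(k5)), rep(1 / sqrt(5), 5), tolerance = 1e-10)

  expect_error(eigenvector_scores(igraph::make_empty_graph(0, directed = FALSE)),
               class = "pcanet_error_empty_graph")
})

test_that("eigenvector scores are equivariant under node relabelling", {
  set.seed(4)
  for (rep in 1:5) {
    g <- random_connected_graph(10, 0.3)
    sc <- eigenvector_scores(g)
    perm <- sample(10)
    g2 <- igraph::permute(g, perm)
    sc2 <- eigenvector_scores(g2)
    expect_equal(sc2[names(sc)], sc, tolerance = 1e-8)
  }
})

test_that("top_m breaks boundary ties lexicographically and matches sort-then-slice", {
  sc <- c(b = 0.5, a = 0.5, d = 0.9, c = 0.5)
  expect_identical(top_m(sc, 2), c("a", "d"))
  expect_identical(top_m(sc, 4), c("a", "b", "c", "d"))
  expect_error(top_m(sc, 5), class = "pcanet_error_bad_config")
  set.seed(8)
  for (rep in 1:5) {
    sc <- setNames(round(runif(12), 1), sprintf("n%02d", sample(12)))
    m <- sample(1:12, 1)
    ord <- names(sc)[order(-sc, names(sc))]
    expect_identical(top_m(sc, m), sort(ord[seq_len(m)]))
  }
})

test_that("keyplayer fitness matches closed forms and a BFS brute force", {
  g <- star_graph(4)
  expect_equal(kpp_fitness(g, "c0"), 4 / 5)
  expect_equal(kpp_fitness(g, c("c0", paste0("l0", 1:4))), 0)
  expect_equal(kpp_fitness(g, "l01"), (1 + 3 * 0.5) / 5)
  expect_error(kpp_fitness(g, character(0)), class = "pcanet_error_empty_set")
  expect_error(kpp_fitness(g, "nope"), class = "pcanet_error_unknown_node")

  set.seed(14)
  for (rep in 1:10) {
    g <- igraph::sample_gnp(10, 0.25)
    igraph::V(g)$name <- sprintf("v%02d", 1:10)
    D <- bfs_dist_matrix(graph_edge_idx(g), 10)
    S_idx <- sample(10, sample(1:4, 1))
    expect_equal(kpp_fitness(g, sprintf("v%02d", S_idx)),
                 oracle_kpp_fitness(D, S_idx), tolerance = 1e-12)
  }
})

test_that("keyplayer selection finds the structural optimum on canonical graphs", {
  g <- star_graph(6)
  expect_identical(kpp_select(g, 1, seed = 1), "c0")
  # two disjoint stars: one centre per component
  g2 <- igraph::disjoint_union(star_graph(5, center = "cA", leaf_prefix = "a"),
                               star_graph(4, center = "cB", leaf_prefix = "b"))
  expect_identical(kpp_select(g2, 2, seed = 1), c("cA", "cB"))
})

test_that("swap hill-climbing never falls below the greedy seeding", {
  set.seed(23)
  for (rep in 1:8) {
    g <- random_connected_graph(11, 0.25)
    m <- sample(2:4, 1)
    greedy <- kpp_select(g, m, kp_max_sweeps = 0, seed = rep)
    improved <- kpp_select(g, m, kp_max_sweeps = 8, kp_restarts = 2, seed = rep)
    expect_gte(kpp_fitness(g, improved), kpp_fitness(g, greedy) - 1e-12)
  }
})

test_that("selection counts aggregate exactly over ensemble members", {
  net <- random_partial(101, n_resp = 5, n_nonresp = 7, p_rn = 0.4)
  model <- dyad_model(-0.5, 0.05, 0.2)
  ens <- impute_ensemble(net, model, M = 6, seed = 4)
  cfg <- selection_config(m = 4, algorithm = "eigenvector")
  counts <- aggregate_selections(ens, cfg)
  expect_identical(sum(counts), 4L * 6L)
  # matches per-network recomputation
  recount <- table(unlist(lapply(ensemble_networks(ens), function(nw)
    top_m(eigenvector_scores(nw), 4))))
  expect_identical(as.integer(counts), as.integer(recount[names(counts)]))
  # M = 1 gives 0/1 indicators
  one <- aggregate_selections(list(ensemble_network(ens, 1)), cfg)
  expect_true(all(one == 1L))
  expect_identical(sum(one), 4L)
})

test_that("the sufficiency cutoff picks the smallest set closest to the target", {
  counts <- setNames(c(10L, 10L, 7L, 5L, 2L, 1L), letters[1:6])
  attr(counts, "M") <- 10L
  # exhaustive scan oracle
  oracle <- function(counts, m, M) {
    s <- vapply(1:M, function(t) sum(counts >= t), integer(1))
    gaps <- abs(s - m)
    t_best <- max(which(gaps == min(gaps)))
    list(cutoff = t_best, size = s[t_best])
  }
  for (m in 1:6) {
    got <- sufficiency_cutoff(counts, m)
    want <- oracle(counts, m, 10L)
    expect_identical(got$cutoff, want$cutoff)
    expect_identical(length(got$spca_set), as.integer(want$size))
  }
  # every node selected on every network, target = n -> cutoff M, set = all
  all_in <- setNames(rep(5L, 4), letters[1:4])
  res <- sufficiency_cutoff(all_in, 4, M = 5)
  expect_identical(res$cutoff, 5L)
  expect_identical(res$spca_set, letters[1:4])
})

test_that("identical ensemble members give perfectly stable eigenvector selection", {
  net <- random_partial(111, n_resp = 6, n_nonresp = 6, p_rn = 0.4)
  # zero unobserved dyads is impossible with nonrespondents present, so
  # replicate one member: a deterministic algorithm must select identically
  model <- dyad_model(50, 0, 0)  # p = 1 for every unobserved dyad
  ens <- impute_ensemble(net, model, M = 8, seed = 2)
  cfg <- selection_config(m = 5, algorithm = "eigenvector")
  res <- select_pcas(net, ens, cfg)
  expect_true(all(res$counts %in% c(0L, 8L)))
  expect_identical(res$cutoff, 8L)
  # with no unobserved dyads at all, ensemble equals observed network
  rr <- partial_network(
    data.frame(node_id = sprintf("p%d", 1:6), is_respondent = TRUE),
    data.frame(source = c("p1", "p1", "p2", "p3", "p4"),
               target = c("p2", "p3", "p3", "p4", "p5")))
  ens0 <- impute_ensemble(rr, model, M = 5, seed = 1)
  res0 <- select_pcas(rr, ens0, selection_config(m = 3, algorithm = "eigenvector"))
  expect_identical(res0$spca_set, res0$observed_set)
  expect_true(all(res0$counts == 5L))
})

test_that("selection results serialize and reload losslessly", {
  net <- random_partial(121, n_resp = 5, n_nonresp = 6, p_rn = 0.4)
  ens <- impute_ensemble(net, dyad_model(-0.5, 0.08, 0.1), M = 4, seed = 9)
  res <- select_pcas(net, ens, selection_config(m = 4, algorithm = "keyplayer", seed = 3))
  p <- tempfile(fileext = ".json")
  write_selection(res, p)
  back <- read_selection(p)
  for (f in c("algorithm", "m", "M", "observed_set", "cutoff", "spca_set")) {
    expect_identical(back[[f]], res[[f]])
  }
  expect_identical(as.integer(back$counts), as.integer(res$counts))
  expect_identical(names(back$counts), names(res$counts))
})

test_that("select_pcas rejects ensembles over a different node set", {
  net <- random_partial(131, n_resp = 4, n_nonresp = 5)
  other <- random_partial(132, n_resp = 4, n_nonresp = 6)
  ens <- impute_ensemble(other, dyad_model(0, 0, 0), M = 2, seed = 1)
  expect_error(select_pcas(net, ens, selection_config(m = 3)),
               class = "pcanet_error_node_mismatch")
})
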