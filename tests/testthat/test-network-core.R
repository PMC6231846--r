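test_that("sociability covariates and dyad statuses follow the observation design", {
  net <- partial_network(
    data.frame(node_id = c("A", "B", "C"),
               is_respondent = c(TRUE, TRUE, FALSE)),
    data.frame(source = c("A", "A"), target = c("B", "C"))
  )
  soc <- setNames(net$nodes$soc_covariate, net$nodes$node_id)
  expect_identical(soc, c(A = 1L, B = 1L, C = 1L))
  expect_identical(dyad_status(net, "B", "C"), "observed_absent")
  expect_identical(dyad_status(net, "A", "B"), "observed_present")
  expect_identical(dyad_status(net, "C", "A"), "observed_present")  # order-free
})

test_that("invalid edge lists raise distinct classed validation errors", {
  nodes <- toy_nodes()
  expect_error(partial_network(nodes, data.frame(source = "A", target = "Z")),
               class = "pcanet_error_unknown_node")
  expect_error(partial_network(nodes, data.frame(source = "A", target = "A")),
               class = "pcanet_error_self_loop")
  expect_error(partial_network(nodes, data.frame(source = c("A", "B"), target = c("B", "A"))),
               class = "pcanet_error_duplicate_edge")
  expect_error(partial_network(nodes, data.frame(source = "C", target = "D")),
               class = "pcanet_error_nonrespondent_edge")
  expect_error(partial_network(rbind(nodes, nodes[1, ]), NULL),
               class = "pcanet_error_duplicate_node")
  # a completed network may carry nonrespondent-nonrespondent edges
  expect_s3_class(complete_network(nodes, data.frame(source = "C", target = "D")),
                  "complete_network")
})

test_that("networks round-trip through write_network/read_network unchanged", {
  net <- random_partial(11, n_resp = 4, n_nonresp = 6)
  expect_equal(nrow(net$edges) > 0, TRUE)
  np <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  write_network(net, np, ep)
  back <- read_network(np, ep)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$edges, net$edges)

  # completed network: imputed flag preserved
  cn <- complete_network(net$nodes,
                         rbind(cbind(net$edges, imputed = FALSE),
                               data.frame(source = "x01", target = "x02", imputed = TRUE)))
  write_network(cn, np, ep)
  back2 <- read_network(np, ep)
  expect_s3_class(back2, "complete_network")
  expect_identical(back2$edges, cn$edges)

  # empty network writes header-only files that read back empty
  empty <- partial_network(toy_nodes(), NULL)
  write_network(empty, np, ep)
  expect_identical(nrow(read_network(np, ep)$edges), 0L)
  expect_error(read_network("no/such/nodes.csv", ep), class = "pcanet_error_missing_file")
})

test_that("dyad counts conserve the total number of dyads", {
  for (seed in 1:5) {
    net <- random_partial(seed, n_resp = 5, n_nonresp = 7)
    dc <- dyad_counts(net)
    expect_identical(dc$n_observed_present + dc$n_observed_absent + dc$n_unobserved,
                     choose(n_nodes(net), 2))
    expect_identical(dc$n_unobserved, choose(7, 2))
  }
})

test_that("apply_boundary matches a brute-force filter and is monotone in k", {
  for (seed in 1:4) {
    net <- random_partial(seed, n_resp = 6, n_nonresp = 12, p_rn = 0.35)
    soc <- setNames(net$nodes$soc_covariate, net$nodes$node_id)
    prev <- NULL
    for (k in 1:4) {
      bounded <- apply_boundary(net, k)
      brute <- sort(net$nodes$node_id[net$nodes$is_respondent | soc >= k])
      expect_identical(bounded$nodes$node_id, brute)
      # retained sociabilities are unchanged by construction
      expect_identical(setNames(bounded$nodes$soc_covariate, bounded$nodes$node_id),
                       soc[bounded$nodes$node_id])
      kept_nr <- bounded$nodes$node_id[!bounded$nodes$is_respondent]
      if (!is.null(prev)) expect_true(all(kept_nr %in% prev))
      prev <- kept_nr
    }
    # k = 1 keeps every nonrespondent with at least one observed tie
    b1 <- apply_boundary(net, 1)
    expect_setequal(b1$nodes$node_id[!b1$nodes$is_respondent],
                    names(soc)[!net$nodes$is_respondent & soc >= 1])
  }
  net <- random_partial(9, n_resp = 4, n_nonresp = 4, p_rn = 0.2)
  expect_warning(apply_boundary(net, 1000L), class = "pcanet_warning_empty_boundary")
})

test_that("boundary_table satisfies its dyad-accounting identities", {
  net <- random_partial(21, n_resp = 8, n_nonresp = 20, p_rn = 0.3)
  tab <- boundary_table(net, 1:5)
  soc_nr <- net$nodes$soc_covariate[!net$nodes$is_respondent]
  for (r in seq_len(nrow(tab))) {
    k <- tab$k[r]
    expect_identical(tab$n_nonresp_retained[r], sum(soc_nr >= k))
    expect_identical(tab$edges_rn_retained[r], sum(soc_nr[soc_nr >= k]))
    expect_equal(tab$unobserved_dyads_nn[r], choose(tab$n_nonresp_retained[r], 2))
    expect_equal(tab$pct_of_respondents[r], floor(1000 * k / 8 + 0.5) / 10)
  }
  expect_error(boundary_table(net, integer(0)), class = "pcanet_error_bad_boundary")
})

test_that("quadrant_summary agrees with brute-force recounting", {
  net <- random_partial(31, n_resp = 6, n_nonresp = 9)
  qs <- quadrant_summary(net)
  resp <- setNames(net$nodes$is_respondent, net$nodes$node_id)
  rr <- sum(resp[net$edges$source] & resp[net$edges$target])
  rn <- sum(xor(resp[net$edges$source], resp[net$edges$target]))
  expect_identical(qs$edges_rr, rr)
  expect_identical(qs$edges_rn, rn)
  expect_equal(qs$density_rr, rr / choose(6, 2))
  expect_equal(qs$density_rn, rn / (6 * 9))
  expect_equal(qs$mean_degree_resp, (2 * rr + rn) / 6)
  expect_equal(qs$mean_degree_nonresp_observed, rn / 9)

  none <- partial_network(toy_nodes(), NULL)
  qs0 <- quadrant_summary(none)
  expect_equal(qs0$density_rr, 0)
  expect_equal(qs0$density_rn, 0)

  solo <- partial_network(data.frame(node_id = c("A", "B"),
                                     is_respondent = c(TRUE, FALSE)), NULL)
  expect_true(is.na(quadrant_summary(solo)$density_rr))
})

test_that("degree distributions bin half-open, count every node, and ignore imputation for respondents", {
  net <- random_partial(41, n_resp = 6, n_nonresp = 10, p_rn = 0.4)
  for (role in c("respondent", "nonrespondent")) {
    h <- degree_distribution(net, role, bin_width = 3)
    expect_identical(sum(h$count), if (role == "respondent") 6L else 10L)
    expect_identical(h$bin_hi - h$bin_lo, rep(3L, nrow(h)))
  }
  # imputing nonrespondent-nonrespondent edges leaves respondent degrees unchanged
  cn <- complete_network(net$nodes,
                         rbind(cbind(net$edges, imputed = FALSE),
                               data.frame(source = "x01", target = "x03", imputed = TRUE)))
  expect_identical(degree_distribution(net, "respondent"),
                   degree_distribution(cn, "respondent"))
  expect_false(identical(degree_distribution(net, "nonrespondent", bin_width = 1),
                         degree_distribution(cn, "nonrespondent", bin_width = 1)))

  solo <- partial_network(data.frame(node_id = "A", is_respondent = TRUE), NULL)
  h1 <- degree_distribution(solo, "respondent")
  expect_identical(h1, data.frame(bin_lo = 0L, bin_hi = 10L, count = 1L))
})

test_that("graphml export keeps the imputed edge attribute", {
  net <- random_partial(51, n_resp = 3, n_nonresp = 4)
  cn <- complete_network(net$nodes,
                         rbind(cbind(net$edges, imputed = FALSE),
                               data.frame(source = "x01", target = "x02", imputed = TRUE)))
  p <- tempfile(fileext = ".graphml")
  write_graphml(cn, p)
  g <- igraph::read_graph(p, format = "graphml")
  expect_identical(sum(igraph::E(g)$imputed), 1)
})
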