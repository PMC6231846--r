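test_that("the dyad design codes responses, sociability sums and mixing correctly", {
  net <- partial_network(
    data.frame(node_id = c("A", "B", "C", "D"),
               is_respondent = c(TRUE, TRUE, FALSE, FALSE)),
    data.frame(source = c("A", "B", "A", "A"), target = c("B", "C", "C", "D"))
  )
  # soc: A = 1 (B), B = 1 (A), C = 2 (A,B), D = 1 (A)
  design <- build_dyad_design(net)
  expect_identical(nrow(design), as.integer(choose(4, 2)))
  row <- function(i, j) design[design$node_i == i & design$node_j == j, ]
  ac <- row("A", "C")
  expect_identical(c(ac$response, ac$soc_sum, ac$is_mixed), c(1L, 3L, 1L))
  cd <- row("C", "D")
  expect_true(is.na(cd$response))
  expect_identical(cd$soc_sum, 3L)
  expect_identical(cd$is_mixed, 0L)
  expect_identical(row("A", "B")$is_mixed, 0L)
  # design row counts on random networks
  for (seed in 1:3) {
    n <- random_partial(seed, n_resp = 5, n_nonresp = 6)
    d <- build_dyad_design(n)
    expect_identical(nrow(d), as.integer(choose(11, 2)))
    expect_identical(sum(is.na(d$response)), as.integer(choose(6, 2)))
    expect_identical(sum(d$response, na.rm = TRUE), nrow(n$edges))
  }
})

test_that("degenerate designs raise separation and collinearity errors", {
  nodes <- data.frame(node_id = c("A", "B", "C"), is_respondent = c(TRUE, TRUE, FALSE))
  expect_error(fit_dyad_model(build_dyad_design(partial_network(nodes, NULL))),
               class = "pcanet_error_separation")
  full <- partial_network(nodes, data.frame(source = c("A", "A", "B"),
                                            target = c("B", "C", "C")))
  expect_error(fit_dyad_model(build_dyad_design(full)),
               class = "pcanet_error_separation")
  # all-respondent network: is_mixed is constant among observed dyads
  rr <- partial_network(
    data.frame(node_id = c("A", "B", "C", "D"), is_respondent = TRUE),
    data.frame(source = c("A", "B"), target = c("B", "C")))
  expect_error(fit_dyad_model(build_dyad_design(rr)),
               class = "pcanet_error_singular_design")
})

test_that("fitted coefficients recover ground truth and carry the study sign pattern", {
  cfg <- generator_config(n_resp = 150, n_nonresp_pool = 310, boundary_k = 15, seed = 42)
  d <- generate_dataset(cfg)
  fit <- fit_dyad_model(build_dyad_design(d$network))
  th <- cfg$theta_true
  expect_lt(abs(fit$theta_edges - th["theta_edges"]) / fit$se_edges, 3.5)
  expect_lt(abs(fit$theta_soc - th["theta_soc"]) / fit$se_soc, 3.5)
  expect_lt(abs(fit$theta_mix - th["theta_mix"]) / fit$se_mix, 3.5)
  # sign pattern reported for the study data: edges < 0, sociability > 0, mixing > 0
  expect_lt(fit$theta_edges, 0)
  expect_gt(fit$theta_soc, 0)
  expect_gt(fit$theta_mix, 0)
})

test_that("estimation error of the sociability slope shrinks as networks grow", {
  sizes <- list(c(40, 85, 4), c(100, 210, 10), c(240, 495, 24))
  n_seeds <- c(10, 8, 5)   # enough replicates that sampling noise does not
                           # mask the expected error decay
  err <- vapply(seq_along(sizes), function(i) {
    sz <- sizes[[i]]
    mean(vapply(seq_len(n_seeds[i]), function(s) {
      cfg <- generator_config(n_resp = sz[1], n_nonresp_pool = sz[2],
                              boundary_k = sz[3], seed = 100 + s)
      fit <- fit_dyad_model(build_dyad_design(generate_dataset(cfg)$network))
      abs(fit$theta_soc - cfg$theta_true[["theta_soc"]]) / cfg$theta_true[["theta_soc"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], err[1] / 2)
})

test_that("imputation fixes observed dyads and draws unobserved ones from the model", {
  net <- random_partial(61, n_resp = 5, n_nonresp = 8, p_rn = 0.4)
  model <- dyad_model(0, 0, 0)   # every unobserved dyad imputed with probability 1/2
  ens <- impute_ensemble(net, model, M = 60, seed = 2)
  n_unobs <- choose(8, 2)
  expect_identical(ens$imputed_edge_counts,
                   vapply(ens$draws, length, integer(1)))
  dens <- mean(ens$imputed_edge_counts) / n_unobs
  expect_lt(abs(dens - 0.5), 4 * sqrt(0.25 / (60 * n_unobs)))
  # observed dyads are copied verbatim into every member
  design <- build_dyad_design(net)
  obs <- design[!is.na(design$response), ]
  for (i in c(1, 30, 60)) {
    nw <- ensemble_network(ens, i)
    st <- dyad_status(nw, obs$node_i, obs$node_j)
    expect_identical(st == "observed_present", obs$response == 1L)
    expect_true(all(!nw$edges$imputed[nw$edges$source %in% net$edges$source &
                                        paste(nw$edges$source, nw$edges$target) %in%
                                        paste(net$edges$source, net$edges$target)]))
  }
  # zero unobserved dyads: all members identical to the observed network
  rr <- partial_network(data.frame(node_id = c("A", "B", "C"), is_respondent = TRUE),
                        data.frame(source = "A", target = "B"))
  ens0 <- impute_ensemble(rr, model, M = 3, seed = 1)
  for (i in 1:3) {
    expect_identical(ensemble_network(ens0, i)$edges[, c("source", "target")],
                     rr$edges)
  }
})

test_that("ensemble draws are reproducible member-by-member from the master seed", {
  net <- random_partial(71, n_resp = 4, n_nonresp = 7)
  model <- dyad_model(-1, 0.1, 0.5)
  e1 <- impute_ensemble(net, model, M = 5, seed = 10)
  e2 <- impute_ensemble(net, model, M = 5, seed = 10)
  expect_identical(e1$draws, e2$draws)
  e3 <- impute_ensemble(net, model, M = 5, seed = 11)
  expect_false(identical(e1$draws, e3$draws))
})

test_that("the toggling sampler matches the independence scheme it mirrors", {
  net <- random_partial(81, n_resp = 5, n_nonresp = 7, p_rn = 0.35)
  model <- dyad_model(-0.4, 0.05, 0.3)
  # 0 steps returns the initial completion
  t0 <- toggling_sampler(net, model, n_steps = 0, seed = 1)
  expect_identical(t0$edges[, c("source", "target")], net$edges)
  # long-run edge count close to the sum of per-dyad probabilities
  unobs <- build_dyad_design(net)
  unobs <- unobs[is.na(unobs$response), ]
  p <- plogis(model$theta_edges + model$theta_soc * unobs$soc_sum)
  counts <- vapply(1:40, function(s) {
    nw <- toggling_sampler(net, model, n_steps = 800, seed = 100 + s)
    sum(nw$edges$imputed)
  }, numeric(1))
  tol <- 4 * sqrt(sum(p * (1 - p)) / 40)
  expect_lt(abs(mean(counts) - sum(p)), tol)
  # observed dyads never altered by toggling
  resp <- setNames(net$nodes$is_respondent, net$nodes$node_id)
  nw <- toggling_sampler(net, model, n_steps = 2000, seed = 7)
  kept <- nw$edges[!nw$edges$imputed, c("source", "target")]
  rownames(kept) <- NULL
  expect_identical(kept, net$edges)
})

test_that("diagnostics arithmetic matches brute force and flags stable ensembles", {
  net <- random_partial(91, n_resp = 4, n_nonresp = 6)
  ens <- impute_ensemble(net, dyad_model(-0.5, 0.1, 0), M = 20, seed = 3)
  diag <- imputation_diagnostics(ens)
  counts <- ens$imputed_edge_counts
  expect_equal(diag$mean_imputed_edges, mean(counts))
  expect_equal(diag$max_deviation_pct, max(abs(counts - mean(counts))) / mean(counts) * 100)
  expect_equal(diag$mean_imputed_nn_density, mean(counts) / choose(6, 2))
  # a model certain of every dyad gives identical members and zero deviation
  sure <- impute_ensemble(net, dyad_model(50, 0, 0), M = 4, seed = 1)
  expect_equal(imputation_diagnostics(sure)$max_deviation_pct, 0)
})

test_that("positive mixing dampens imputed nonrespondent ties relative to mixed ties", {
  cfg <- generator_config(n_resp = 100, n_nonresp_pool = 210, boundary_k = 10, seed = 5)
  d <- generate_dataset(cfg)
  fit <- fit_dyad_model(build_dyad_design(d$network))
  expect_gt(fit$theta_mix, 0)
  soc_sum <- 60
  p_nn <- plogis(fit$theta_edges + fit$theta_soc * soc_sum)
  p_mixed <- plogis(fit$theta_edges + fit$theta_soc * soc_sum + fit$theta_mix)
  expect_lt(p_nn, p_mixed)
})
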