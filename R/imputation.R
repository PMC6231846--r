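#' Per-dyad design for the three-parameter dyad model
#'
#' Expands a partial network into one row per dyad with the response coded
#' as in the observation design (1 observed present, 0 observed absent, NA
#' unobserved), the sociability sum `soc_sum = soc_i + soc_j`, and the
#' selective-mixing indicator `is_mixed` (1 iff exactly one endpoint is a
#' respondent). Rows with missing response are excluded from estimation but
#' retained for prediction.
#'
#' @param net a `partial_network`.
#' @return data frame with `choose(n, 2)` rows and columns `node_i`,
#'   `node_j` (canonical order), `response`, `soc_sum`, `is_mixed`.
#' @export
build_dyad_design <- function(net) {
  stopifnot(inherits(net, "partial_network"))
  ids <- net$nodes$node_id          # already sorted lexicographically
  n <- length(ids)
  if (n < 2) {
    return(data.frame(node_i = character(0), node_j = character(0),
                      response = integer(0), soc_sum = integer(0),
                      is_mixed = integer(0), stringsAsFactors = FALSE))
  }
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n), use.names = FALSE)
  resp <- net$nodes$is_respondent
  soc <- net$nodes$soc_covariate
  design <- data.frame(
    node_i = ids[i], node_j = ids[j],
    response = 0L,
    soc_sum = soc[i] + soc[j],
    is_mixed = as.integer(xor(resp[i], resp[j])),
    stringsAsFactors = FALSE
  )
  design$response[!resp[i] & !resp[j]] <- NA_integer_
  key <- paste(design$node_i, design$node_j, sep = "\r")
  present <- key %in% paste(net$edges$source, net$edges$target, sep = "\r")
  design$response[present & !is.na(design$response)] <- 1L
  design
}

#' Fit the dyad-independent ERGM by logistic maximum likelihood
#'
#' Fits `logit P(tie) = theta_edges + theta_soc * soc_sum + theta_mix *
#' is_mixed` over the observed dyads. Because all three statistics are
#' dyad-independent (edge count, sociability sum with frozen covariates,
#' mixed-edge count), the ERGM likelihood conditional on the observed dyads
#' factorises over dyads, and this logistic MLE *is* the ERGM MLE — no MCMC
#' is needed. Standard errors come from the observed information matrix.
#'
#' @param design output of [build_dyad_design()].
#' @return an object of class `dyad_model` with elements `theta_edges`,
#'   `theta_soc`, `theta_mix`, `se_edges`, `se_soc`, `se_mix`,
#'   `n_obs_dyads`, `vcov`.
#' @export
fit_dyad_model <- function(design) {
  obs <- design[!is.na(design$response), , drop = FALSE]
  if (nrow(obs) == 0) {
    pn_stop("pcanet_error_no_observed_dyads", "design contains no observed dyads")
  }
  if (all(obs$response == 1) || all(obs$response == 0)) {
    pn_stop("pcanet_error_separation",
            "all observed dyads are present (or all absent); the logistic MLE does not exist")
  }
  X <- cbind(1, obs$soc_sum, obs$is_mixed)
  if (qr(X)$rank < ncol(X)) {
    pn_stop("pcanet_error_singular_design",
            "design is collinear (constant soc_sum or is_mixed among observed dyads)")
  }
  fit <- stats::glm(response ~ soc_sum + is_mixed, family = stats::binomial(),
                    data = obs)
  if (!fit$converged) {
    pn_stop("pcanet_error_separation", "logistic fit did not converge (quasi-separation)")
  }
  est <- stats::coef(fit)
  vc <- stats::vcov(fit)
  se <- sqrt(diag(vc))
  structure(list(
    theta_edges = unname(est[1]), theta_soc = unname(est[2]), theta_mix = unname(est[3]),
    se_edges = unname(se[1]), se_soc = unname(se[2]), se_mix = unname(se[3]),
    n_obs_dyads = nrow(obs),
    vcov = vc
  ), class = "dyad_model")
}

#' @export
print.dyad_model <- function(x, ...) {
  cat("Dyad-independent ERGM fit (logistic MLE over observed dyads)\n")
  cat(sprintf("  edges       %8.3f (SE %.4g)\n", x$theta_edges, x$se_edges))
  cat(sprintf("  sociability %8.4f (SE %.4g)\n", x$theta_soc, x$se_soc))
  cat(sprintf("  mixing      %8.3f (SE %.4g)\n", x$theta_mix, x$se_mix))
  cat(sprintf("  observed dyads: %d\n", x$n_obs_dyads))
  invisible(x)
}

#' Construct a dyad model from known coefficients
#'
#' Useful for imputing from ground-truth parameters or for closed-form
#' checks; standard errors default to `NA`.
#'
#' @param theta_edges,theta_soc,theta_mix log-odds coefficients.
#' @return a `dyad_model`.
#' @export
dyad_model <- function(theta_edges, theta_soc, theta_mix) {
  structure(list(
    theta_edges = theta_edges, theta_soc = theta_soc, theta_mix = theta_mix,
    se_edges = NA_real_, se_soc = NA_real_, se_mix = NA_real_,
    n_obs_dyads = 0L, vcov = NULL
  ), class = "dyad_model")
}

unobserved_dyads <- function(net) {
  design <- build_dyad_design(net)
  design[is.na(design$response), c("node_i", "node_j", "soc_sum"), drop = FALSE]
}

## Predicted tie probability for unobserved dyads. They are always
## nonrespondent-nonrespondent, hence is_mixed = 0.
predict_unobserved <- function(model, unobs) {
  stats::plogis(model$theta_edges + model$theta_soc * unobs$soc_sum)
}

#' Draw multiple imputations of the unobserved dyads
#'
#' Each unobserved dyad is drawn independently Bernoulli with log-odds
#' `theta_edges + theta_soc * soc_sum` (unobserved dyads join two
#' nonrespondents, so the mixing term never applies); observed dyads are
#' copied verbatim into every completed network. Under dyad independence
#' this independent-Bernoulli scheme draws exactly from the fitted model's
#' conditional distribution given the observed dyads — the Metropolis
#' toggling sampler ([toggling_sampler()]) has the same stationary law and
#' is retained only as a fidelity check.
#'
#' Imputation `i` uses its own stream seeded at `seed + i`, so ensembles
#' are reproducible member-by-member.
#'
#' @param net a `partial_network`.
#' @param model a `dyad_model`.
#' @param M number of imputations (the study convention is 100).
#' @param seed master integer seed.
#' @return an object of class `imputed_ensemble` with fields `M`, `seed`,
#'   `imputed_edge_counts`, and the per-imputation draws; members are
#'   materialised with [ensemble_network()].
#' @export
impute_ensemble <- function(net, model, M = 100, seed = 1) {
  stopifnot(inherits(net, "partial_network"), inherits(model, "dyad_model"))
  M <- as.integer(M)
  if (is.na(M) || M < 1) pn_stop("pcanet_error_bad_config", "M must be a positive integer")
  unobs <- unobserved_dyads(net)
  p <- predict_unobserved(model, unobs)
  draws <- vector("list", M)
  for (m in seq_len(M)) {
    set.seed(seed + m)
    ## short burn-in: the first draws after seeding with consecutive
    ## integers carry a slight initialization bias
    stats::runif(32)
    draws[[m]] <- which(stats::runif(length(p)) < p)
  }
  structure(list(
    base = net,
    unobserved = unobs,
    p_unobserved = p,
    draws = draws,
    imputed_edge_counts = vapply(draws, length, integer(1)),
    M = M,
    seed = as.integer(seed),
    model = model
  ), class = "imputed_ensemble")
}

#' @export
print.imputed_ensemble <- function(x, ...) {
  cat(sprintf("imputed_ensemble: M = %d completed networks, %d unobserved dyads, seed %d\n",
              x$M, nrow(x$unobserved), x$seed))
  cat(sprintf("  imputed edges per network: mean %.1f, range %d-%d\n",
              mean(x$imputed_edge_counts), min(x$imputed_edge_counts),
              max(x$imputed_edge_counts)))
  invisible(x)
}

#' Materialise one member of an imputed ensemble
#'
#' @param ens an `imputed_ensemble`.
#' @param i member index in `1:M`.
#' @return a `complete_network` agreeing with the base partial network on
#'   all observed dyads; imputed edges carry `imputed = TRUE`.
#' @export
ensemble_network <- function(ens, i) {
  stopifnot(inherits(ens, "imputed_ensemble"), i >= 1, i <= ens$M)
  idx <- ens$draws[[i]]
  obs <- ens$base$edges[, c("source", "target"), drop = FALSE]
  obs$imputed <- FALSE
  imp <- ens$unobserved[idx, c("node_i", "node_j"), drop = FALSE]
  names(imp) <- c("source", "target")
  if (nrow(imp) > 0) imp$imputed <- TRUE
  complete_network(ens$base$nodes, rbind(obs, imp))
}

#' Ensemble as a list of completed networks
#'
#' @param ens an `imputed_ensemble`.
#' @return list of `complete_network` objects of length `M`.
#' @export
ensemble_networks <- function(ens) {
  lapply(seq_len(ens$M), function(i) ensemble_network(ens, i))
}

#' Metropolis toggling sampler over the unobserved dyads
#'
#' Reproduces the constrained MCMC procedure: observed dyads are fixed and
#' only unobserved dyads are candidates for toggling. Each step picks one
#' unobserved dyad uniformly and toggles it with the Metropolis acceptance
#' probability `min(1, exp(+-eta))`, where `eta` is that dyad's log-odds
#' under the model — under dyad independence the acceptance ratio depends
#' only on the toggled dyad, and the stationary distribution is identical
#' to the independent-Bernoulli scheme of [impute_ensemble()].
#'
#' @param net a `partial_network`.
#' @param model a `dyad_model`.
#' @param n_steps number of toggle proposals; 0 returns the initial
#'   completion unchanged.
#' @param seed integer seed.
#' @param init initial state of the unobserved dyads: `"absent"` (default)
#'   or a logical vector over the unobserved dyads in canonical order.
#' @return a `complete_network`.
#' @export
toggling_sampler <- function(net, model, n_steps, seed = 1, init = "absent") {
  stopifnot(inherits(net, "partial_network"), inherits(model, "dyad_model"))
  unobs <- unobserved_dyads(net)
  eta <- model$theta_edges + model$theta_soc * unobs$soc_sum
  state <- if (identical(init, "absent")) rep(FALSE, nrow(unobs)) else as.logical(init)
  stopifnot(length(state) == nrow(unobs))
  set.seed(seed)
  if (n_steps > 0 && nrow(unobs) > 0) {
    picks <- sample.int(nrow(unobs), n_steps, replace = TRUE)
    logu <- log(stats::runif(n_steps))
    for (s in seq_len(n_steps)) {
      d <- picks[s]
      ## toggling on gains +eta in log-probability, toggling off gains -eta
      delta <- if (state[d]) -eta[d] else eta[d]
      if (logu[s] < delta) state[d] <- !state[d]
    }
  }
  obs <- net$edges[, c("source", "target"), drop = FALSE]
  obs$imputed <- FALSE
  imp <- unobs[state, c("node_i", "node_j"), drop = FALSE]
  names(imp) <- c("source", "target")
  if (nrow(imp) > 0) imp$imputed <- TRUE
  complete_network(net$nodes, rbind(obs, imp))
}

#' Diagnostics for an imputed ensemble
#'
#' Reports the mean, minimum and maximum number of imputed edges across the
#' ensemble, the maximum deviation from the mean as a percentage of the
#' mean (the criterion used to judge that M imputations suffice), and the
#' mean imputed density of the nonrespondent-nonrespondent quadrant.
#'
#' @param ens an `imputed_ensemble` with `M >= 2`.
#' @return named list of diagnostics.
#' @export
imputation_diagnostics <- function(ens) {
  stopifnot(inherits(ens, "imputed_ensemble"))
  if (ens$M < 2) pn_stop("pcanet_error_bad_config", "diagnostics require M >= 2")
  counts <- ens$imputed_edge_counts
  mu <- mean(counts)
  n_nonresp <- sum(!ens$base$nodes$is_respondent)
  nn_dyads <- choose(n_nonresp, 2)
  list(
    M = ens$M,
    mean_imputed_edges = mu,
    min_imputed_edges = min(counts),
    max_imputed_edges = max(counts),
    max_deviation_pct = if (mu > 0) max(abs(counts - mu)) / mu * 100 else 0,
    mean_imputed_nn_density = if (nn_dyads > 0) mu / nn_dyads else NA_real_
  )
}
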