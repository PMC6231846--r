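#' Self-consistent ground-truth coefficients for the synthetic generator
#'
#' Derives the three log-odds parameters of the ground-truth dyad model from
#' the target quadrant structure, so that the model the generator simulates
#' from is the same model the estimation step recovers:
#'
#' * `theta_soc = 1 / (n_resp * d_rn * (1 - d_rn))` — the logit-scale slope
#'   of the mean respondent-nonrespondent density `d_rn` with respect to a
#'   one-friend change in degree, i.e. the unique slope under which a node's
#'   expected degree-with-respondents is a fixed point of its own
#'   sociability;
#' * `theta_edges` matches the respondent-respondent density at the mean
#'   respondent sociability;
#' * `theta_mix` lifts mixed dyads to the target respondent-nonrespondent
#'   density at the mean mixed-dyad sociability.
#'
#' @param n_resp number of respondents.
#' @param p_rr respondent-respondent tie probability.
#' @param density_rn target respondent-nonrespondent density among retained
#'   nonrespondents.
#' @param mean_soc_nonresp target mean degree-with-respondents of retained
#'   nonrespondents.
#' @return named numeric vector `c(theta_edges, theta_soc, theta_mix)`.
#' @export
calibrated_theta <- function(n_resp = 298, p_rr = 0.074,
                             density_rn = 0.151,
                             mean_soc_nonresp = density_rn * n_resp) {
  theta_soc <- 1 / (n_resp * density_rn * (1 - density_rn))
  cbar_r <- (n_resp - 1) * p_rr
  theta_edges <- stats::qlogis(p_rr) - theta_soc * 2 * cbar_r
  theta_mix <- stats::qlogis(density_rn) - theta_edges -
    theta_soc * (cbar_r + mean_soc_nonresp)
  c(theta_edges = theta_edges, theta_soc = theta_soc, theta_mix = theta_mix)
}

#' Configuration for the synthetic-network generator
#'
#' Defaults emulate the empirical structure of the motivating Facebook
#' study: 298 respondents, a pool of nonrespondents of whom roughly 587
#' survive the 30-friend boundary, a respondent-respondent density near
#' 7.4%, a respondent-nonrespondent density near 15.1% among retained
#' nonrespondents, and right-skewed degree distributions.
#'
#' @param n_resp number of respondents.
#' @param n_nonresp_pool size of the nonrespondent pool before the boundary.
#' @param p_rr respondent-respondent tie probability.
#' @param sociability_shape,sociability_rate shape and rate of the gamma
#'   distribution from which each nonrespondent draws a latent sociability
#'   propensity, expressed on the expected degree-with-respondents scale.
#'   The default rate places the propensity mean at `0.146 * n_resp`
#'   (slightly below the 15.1% operating density, compensating the upward
#'   drift induced by boundary truncation), so the distribution scales with
#'   the number of respondents.
#' @param theta_true ground-truth log-odds `c(theta_edges, theta_soc,
#'   theta_mix)` of the dyad model; defaults to [calibrated_theta()].
#' @param boundary_k boundary threshold applied by [generate_dataset()].
#' @param seed integer seed; every random draw in the generator flows from it.
#' @param nn_covariate covariate driving nonrespondent-nonrespondent dyads:
#'   `"degree"` (default) uses the realized degree-with-respondents, exactly
#'   matching the estimand of the imputation model; `"propensity"` is a
#'   misspecification toggle that uses the latent propensity instead.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_resp = 298,
                             n_nonresp_pool = 615,
                             p_rr = 0.074,
                             sociability_shape = 30,
                             sociability_rate = NULL,
                             theta_true = NULL,
                             boundary_k = 30,
                             seed = 1,
                             nn_covariate = c("degree", "propensity")) {
  nn_covariate <- match.arg(nn_covariate)
  if (is.na(p_rr) || p_rr < 0 || p_rr >= 1) {
    pn_stop("pcanet_error_bad_config", "p_rr must lie in [0, 1)")
  }
  if (is.null(sociability_rate)) sociability_rate <- sociability_shape / (0.146 * n_resp)
  if (is.null(theta_true)) theta_true <- calibrated_theta(n_resp = n_resp, p_rr = p_rr)
  theta_true <- as.numeric(theta_true)
  if (length(theta_true) != 3 || anyNA(theta_true) || any(!is.finite(theta_true))) {
    pn_stop("pcanet_error_bad_config", "theta_true must be three finite log-odds values")
  }
  names(theta_true) <- c("theta_edges", "theta_soc", "theta_mix")
  cfg <- list(
    n_resp = as.integer(n_resp), n_nonresp_pool = as.integer(n_nonresp_pool),
    p_rr = p_rr, sociability_shape = sociability_shape,
    sociability_rate = sociability_rate, theta_true = theta_true,
    boundary_k = as.integer(boundary_k), seed = as.integer(seed),
    nn_covariate = nn_covariate
  )
  if (cfg$n_resp < 2 || cfg$n_nonresp_pool < 1) {
    pn_stop("pcanet_error_bad_config", "n_resp must be >= 2 and n_nonresp_pool >= 1")
  }
  if (is.na(cfg$p_rr) || cfg$p_rr < 0 || cfg$p_rr >= 1) {
    pn_stop("pcanet_error_bad_config", "p_rr must lie in [0, 1)")
  }
  if (cfg$sociability_shape <= 0 || cfg$sociability_rate <= 0) {
    pn_stop("pcanet_error_bad_config", "sociability parameters must be positive")
  }
  if (cfg$boundary_k < 1) {
    pn_stop("pcanet_error_bad_config", "boundary_k must be >= 1")
  }
  ## degenerate regime: the model would saturate essentially every
  ## nonrespondent-nonrespondent dyad
  mean_prop <- sociability_shape / sociability_rate
  if (stats::plogis(theta_true[1] + theta_true[2] * 2 * mean_prop) > 0.99) {
    pn_stop("pcanet_error_degenerate_config",
            "expected nonrespondent-nonrespondent density is ~1; config rejected as degenerate")
  }
  structure(cfg, class = "generator_config")
}

node_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(as.character(n))), seq_len(n))
}

#' Generate a complete synthetic network with known ground truth
#'
#' Simulation proceeds quadrant by quadrant, each stage conditioning on
#' covariates realized in earlier stages so that the observed quadrants
#' follow the same dyad model the estimation step fits:
#'
#' 1. respondent-respondent dyads are independent Bernoulli(`p_rr`); the
#'    realized respondent degrees become the respondent sociability
#'    covariates;
#' 2. each nonrespondent draws a latent gamma propensity on the expected
#'    degree scale; respondent-nonrespondent dyads are Bernoulli with
#'    log-odds `theta_edges + theta_soc * (soc_r + propensity_n) +
#'    theta_mix`, where `soc_r` is the respondent's realized sociability;
#' 3. nonrespondent-nonrespondent dyads are Bernoulli with log-odds
#'    `theta_edges + theta_soc * (c_i + c_j)`, where `c` is the realized
#'    degree-with-respondents from step 2 (or the latent propensity when the
#'    `nn_covariate = "propensity"` misspecification toggle is on).
#'
#' @param cfg a [generator_config()].
#' @return a `complete_network` whose `truth` attribute records the
#'   ground-truth parameters, the latent propensities and the config.
#' @export
generate_complete_network <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  th <- cfg$theta_true
  nr <- cfg$n_resp
  np <- cfg$n_nonresp_pool
  resp_ids <- node_ids("R", nr)
  nonresp_ids <- node_ids("N", np)

  ## step 1: respondent-respondent quadrant
  rr_i <- rep(seq_len(nr - 1), times = (nr - 1):1)
  rr_j <- unlist(lapply(seq_len(nr - 1), function(i) (i + 1):nr), use.names = FALSE)
  y_rr <- stats::rbinom(length(rr_i), 1, cfg$p_rr) == 1
  soc_r <- tabulate(c(rr_i[y_rr], rr_j[y_rr]), nbins = nr)

  ## step 2: respondent-nonrespondent quadrant, conditioned on soc_r
  propensity <- stats::rgamma(np, shape = cfg$sociability_shape, rate = cfg$sociability_rate)
  eta_rn <- outer(th[["theta_soc"]] * soc_r,
                  th[["theta_edges"]] + th[["theta_mix"]] + th[["theta_soc"]] * propensity,
                  "+")
  y_rn <- matrix(stats::rbinom(length(eta_rn), 1, stats::plogis(eta_rn)) == 1, nr, np)
  soc_n <- colSums(y_rn)

  ## step 3: nonrespondent-nonrespondent quadrant, conditioned on realized
  ## degree-with-respondents (estimand of the imputation model)
  cov_n <- if (cfg$nn_covariate == "degree") soc_n else propensity
  nn_i <- rep(seq_len(np - 1), times = (np - 1):1)
  nn_j <- unlist(lapply(seq_len(np - 1), function(i) (i + 1):np), use.names = FALSE)
  eta_nn <- th[["theta_edges"]] + th[["theta_soc"]] * (cov_n[nn_i] + cov_n[nn_j])
  y_nn <- stats::rbinom(length(eta_nn), 1, stats::plogis(eta_nn)) == 1

  edges <- rbind(
    data.frame(source = resp_ids[rr_i[y_rr]], target = resp_ids[rr_j[y_rr]],
               stringsAsFactors = FALSE),
    data.frame(source = resp_ids[row(y_rn)[y_rn]], target = nonresp_ids[col(y_rn)[y_rn]],
               stringsAsFactors = FALSE),
    data.frame(source = nonresp_ids[nn_i[y_nn]], target = nonresp_ids[nn_j[y_nn]],
               stringsAsFactors = FALSE)
  )
  nodes <- data.frame(
    node_id = c(resp_ids, nonresp_ids),
    is_respondent = rep(c(TRUE, FALSE), c(nr, np)),
    stringsAsFactors = FALSE
  )
  net <- complete_network(nodes, edges)
  attr(net, "truth") <- list(
    theta_true = th,
    propensity = stats::setNames(propensity, nonresp_ids),
    config = cfg
  )
  net
}

#' Mask the nonrespondent-nonrespondent dyads of a complete network
#'
#' Removes every edge between two nonrespondents, turning those dyads into
#' unobserved ones, and stores their true states separately so that
#' imputation can later be evaluated against the ground truth. Observed
#' quadrants are untouched.
#'
#' @param cnet a `complete_network`.
#' @return list with `network` (a `partial_network`) and `hidden_truth`
#'   (data frame of all nonrespondent-nonrespondent dyads with their true
#'   0/1 state, in canonical order).
#' @export
mask_nonrespondent_dyads <- function(cnet) {
  stopifnot(inherits(cnet, "complete_network"))
  resp <- respondent_flags(cnet)
  nn_edge <- !resp[cnet$edges$source] & !resp[cnet$edges$target]
  nonresp_ids <- sort(cnet$nodes$node_id[!cnet$nodes$is_respondent])
  m <- length(nonresp_ids)
  if (m >= 2) {
    i <- rep(seq_len(m - 1), times = (m - 1):1)
    j <- unlist(lapply(seq_len(m - 1), function(a) (a + 1):m), use.names = FALSE)
    hidden <- data.frame(source = nonresp_ids[i], target = nonresp_ids[j],
                         stringsAsFactors = FALSE)
    key <- paste(hidden$source, hidden$target, sep = "\r")
    nn <- cnet$edges[nn_edge, , drop = FALSE]
    hidden$present <- key %in% paste(nn$source, nn$target, sep = "\r")
  } else {
    hidden <- data.frame(source = character(0), target = character(0),
                         present = logical(0), stringsAsFactors = FALSE)
  }
  net <- partial_network(cnet$nodes,
                         cnet$edges[!nn_edge, c("source", "target"), drop = FALSE])
  list(network = net, hidden_truth = hidden)
}

#' Reassemble a complete network from a masked one and its hidden truth
#'
#' Inverse of [mask_nonrespondent_dyads()].
#'
#' @param masked list as returned by [mask_nonrespondent_dyads()].
#' @return a `complete_network`.
#' @export
unmask_nonrespondent_dyads <- function(masked) {
  hid <- masked$hidden_truth
  edges <- rbind(
    masked$network$edges[, c("source", "target"), drop = FALSE],
    hid[hid$present, c("source", "target"), drop = FALSE]
  )
  complete_network(masked$network$nodes, edges)
}

#' Generate a partially observed dataset with known ground truth
#'
#' Composition of the full study design: generate a complete network, apply
#' the boundary specification `cfg$boundary_k`, then mask the
#' nonrespondent-nonrespondent dyads. Optionally writes the node table, edge
#' list and a truth JSON to `dir`.
#'
#' @param cfg a [generator_config()].
#' @param dir optional output directory.
#' @return list with `network` (the bounded `partial_network`), `complete`
#'   (the bounded `complete_network`), `hidden_truth` (true states of the
#'   masked dyads) and `truth` (parameters, propensities, config).
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  cnet <- generate_complete_network(cfg)
  truth <- attr(cnet, "truth")
  bounded <- apply_boundary(cnet, cfg$boundary_k)
  masked <- mask_nonrespondent_dyads(bounded)
  out <- list(network = masked$network, complete = bounded,
              hidden_truth = masked$hidden_truth, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_network(out$network, file.path(dir, "nodes.csv"), file.path(dir, "edges.csv"))
    jsonlite::write_json(
      list(theta_true = as.list(truth$theta_true),
           seed = cfg$seed,
           hidden_truth = out$hidden_truth),
      file.path(dir, "truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  out
}
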