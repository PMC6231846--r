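#' Sensitivity of a PCA algorithm to the imputation
#'
#' Sensitivity is the overlap between the PCAs identified on the observed
#' network and the sPCAs identified across the imputed networks: for each
#' respondent-status class, the denominator is the number of sPCAs of that
#' class and the numerator the number of those that were also PCAs on the
#' observed network.
#'
#' @param observed_set PCA ids selected on the observed network.
#' @param spca_set sPCA ids (ensemble selection meeting the cutoff).
#' @param respondent_flags named logical vector over the node universe.
#' @return data frame with rows `respondent`, `nonrespondent`, `overall`
#'   and columns `numerator`, `denominator`, `proportion` (NA when the
#'   denominator is empty).
#' @export
sensitivity <- function(observed_set, spca_set, respondent_flags) {
  unknown <- setdiff(c(observed_set, spca_set), names(respondent_flags))
  if (length(unknown) > 0) {
    pn_stop("pcanet_error_unknown_node", "set member missing from respondent_flags")
  }
  row_for <- function(ids) {
    num <- sum(ids %in% observed_set)
    den <- length(ids)
    data.frame(numerator = num, denominator = den,
               proportion = if (den > 0) num / den else NA_real_)
  }
  res <- rbind(
    row_for(spca_set[respondent_flags[spca_set]]),
    row_for(spca_set[!respondent_flags[spca_set]]),
    row_for(spca_set)
  )
  cbind(status = c("respondent", "nonrespondent", "overall"), res)
}

stat_mode <- function(x) {
  tab <- table(x)
  vals <- as.integer(names(tab))
  vals[order(-as.integer(tab), vals)][1]   # ties -> smallest value
}

#' Stability of selection counts across imputations
#'
#' Summarises, conditional on a node being selected at least once, the
#' number of imputed networks on which it was selected: mean, sample
#' standard deviation and mode (smallest value on ties), overall and by
#' respondent status.
#'
#' @param counts named selection counts (nodes selected at least once).
#' @param respondent_flags named logical vector.
#' @return data frame with rows `overall`, `respondent`, `nonrespondent`
#'   and columns `n`, `mean`, `sd`, `mode` (all NA when no node of that
#'   status was ever selected).
#' @export
stability_summary <- function(counts, respondent_flags) {
  counts <- counts[counts >= 1]
  if (length(counts) == 0) {
    pn_stop("pcanet_error_empty_set", "no node was selected on any network")
  }
  summarise <- function(x) {
    if (length(x) == 0) {
      return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_, mode = NA_integer_))
    }
    data.frame(n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               mode = stat_mode(x))
  }
  is_resp <- respondent_flags[names(counts)]
  res <- rbind(summarise(as.integer(counts)),
               summarise(as.integer(counts[is_resp])),
               summarise(as.integer(counts[!is_resp])))
  cbind(status = c("overall", "respondent", "nonrespondent"), res)
}

#' Boundary effect on selected nonrespondents
#'
#' Reports the minimum degree-with-respondents among nonrespondent sPCAs.
#' When this minimum equals the boundary threshold `k`, the algorithm is
#' selecting nonrespondents right at the inclusion boundary, a sign that
#' the selection is sensitive to the boundary specification.
#'
#' @param spca_set sPCA node ids.
#' @param nodes node table with `node_id`, `is_respondent`, `soc_covariate`.
#' @param k optional boundary threshold used to flag boundary-driven
#'   selection.
#' @return list with `min_soc_covariate` (NA when no nonrespondent sPCA)
#'   and `at_boundary` (logical, NA when `k` is missing).
#' @export
boundary_effect <- function(spca_set, nodes, k = NULL) {
  sel <- nodes[nodes$node_id %in% spca_set & !nodes$is_respondent, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(list(min_soc_covariate = NA_integer_, at_boundary = NA))
  }
  mn <- min(sel$soc_covariate)
  list(min_soc_covariate = mn,
       at_boundary = if (is.null(k)) NA else mn == k)
}

#' Overlap between the sPCA sets of two algorithms
#'
#' @param spca_sets named list of two node-id vectors.
#' @param respondent_flags named logical vector.
#' @return list with `n_intersection`, `n_union` and a respondent /
#'   nonrespondent breakdown of the intersection.
#' @export
algorithm_overlap <- function(spca_sets, respondent_flags) {
  stopifnot(length(spca_sets) == 2)
  a <- spca_sets[[1]]
  b <- spca_sets[[2]]
  both <- intersect(a, b)
  list(
    n_intersection = length(both),
    n_union = length(union(a, b)),
    n_intersection_respondent = sum(respondent_flags[both]),
    n_intersection_nonrespondent = sum(!respondent_flags[both])
  )
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) NA_real_ else length(intersect(a, b)) / u
}

#' Full evaluation report for one algorithm
#'
#' Bundles sensitivity, stability, composition and the boundary effect for
#' a [select_pcas()] result; every reported proportion is accompanied by
#' its numerator and denominator so it can be recomputed.
#'
#' @param result a `selection_result`.
#' @param net the observed `partial_network`.
#' @param k optional boundary threshold for the boundary-effect flag.
#' @return an object of class `evaluation_report`.
#' @export
evaluation_report <- function(result, net, k = NULL) {
  flags <- respondent_flags(net)
  structure(list(
    algorithm = result$algorithm,
    sensitivity = sensitivity(result$observed_set, result$spca_set, flags),
    stability = stability_summary(result$counts, flags),
    n_selected_at_least_once = length(result$counts),
    cutoff = result$cutoff,
    n_spca = length(result$spca_set),
    composition = result$composition,
    boundary = boundary_effect(result$spca_set, net$nodes, k = k)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s): cutoff %d, %d sPCAs, %d nodes ever selected\n",
              x$algorithm, x$cutoff, x$n_spca, x$n_selected_at_least_once))
  s <- x$sensitivity
  for (r in seq_len(nrow(s))) {
    cat(sprintf("  sensitivity %-13s %3d/%3d %s\n", s$status[r], s$numerator[r],
                s$denominator[r], format_pct(s$proportion[r])))
  }
  cat(sprintf("  min sociability of nonrespondent sPCAs: %s (at boundary: %s)\n",
              x$boundary$min_soc_covariate, x$boundary$at_boundary))
  invisible(x)
}

#' Boundary sensitivity of the full pipeline
#'
#' Reruns boundary -> fit -> impute -> select -> evaluate for each
#' threshold in `k_values` on the same raw partial network, and measures
#' the stability of the resulting sPCA sets with the Jaccard overlap
#' between consecutive thresholds.
#'
#' @param raw_net an unbounded `partial_network`.
#' @param k_values increasing vector of boundary thresholds.
#' @param config a [selection_config()].
#' @param M ensemble size per threshold.
#' @param seed master seed (shared across thresholds so differences come
#'   from the boundary, not the random stream).
#' @return list with `reports` (one `evaluation_report` per k) and
#'   `jaccard` (data frame of consecutive-k sPCA overlaps; zero rows when
#'   a single k is given).
#' @export
compare_boundaries <- function(raw_net, k_values, config, M = 20, seed = 1) {
  if (length(k_values) == 0) pn_stop("pcanet_error_bad_config", "k_values is empty")
  runs <- lapply(k_values, function(k) {
    bounded <- apply_boundary(raw_net, k)
    model <- fit_dyad_model(build_dyad_design(bounded))
    ens <- impute_ensemble(bounded, model, M = M, seed = seed)
    res <- select_pcas(bounded, ens, config)
    list(k = k, result = res, report = evaluation_report(res, bounded, k = k))
  })
  jac <- data.frame(k_from = integer(0), k_to = integer(0), jaccard = numeric(0))
  if (length(runs) > 1) {
    for (i in seq_len(length(runs) - 1)) {
      jac <- rbind(jac, data.frame(
        k_from = runs[[i]]$k, k_to = runs[[i + 1]]$k,
        jaccard = jaccard(runs[[i]]$result$spca_set, runs[[i + 1]]$result$spca_set)
      ))
    }
  }
  list(reports = stats::setNames(lapply(runs, `[[`, "report"), paste0("k", k_values)),
       results = stats::setNames(lapply(runs, `[[`, "result"), paste0("k", k_values)),
       jaccard = jac)
}
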