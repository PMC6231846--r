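#' @keywords internal
pn_stop <- function(class, msg) {
  cnd <- structure(
    class = c(class, "pcanet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cnd)
}

#' @keywords internal
pn_warn <- function(class, msg) {
  cnd <- structure(
    class = c(class, "pcanet_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cnd)
}

## Put each undirected edge into canonical form (source < target, rows sorted),
## so that edge sets compare and serialize deterministically.
canonical_edges <- function(edges) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  flip <- src > tgt
  tmp <- src[flip]
  src[flip] <- tgt[flip]
  tgt[flip] <- tmp
  edges$source <- src
  edges$target <- tgt
  edges[order(edges$source, edges$target), , drop = FALSE]
}

## Degree counting only respondent neighbours ("sociability" covariate).
compute_soc_covariate <- function(node_id, is_respondent, edges) {
  resp <- node_id[is_respondent]
  ends <- c(
    edges$source[edges$target %in% resp],
    edges$target[edges$source %in% resp]
  )
  counts <- table(factor(ends, levels = node_id))
  as.integer(counts)
}

validate_network_edges <- function(nodes, edges, allow_nonrespondent_edges) {
  ids <- nodes$node_id
  if (anyDuplicated(ids)) {
    pn_stop("pcanet_error_duplicate_node", "node table contains duplicated node ids")
  }
  unknown <- setdiff(unique(c(edges$source, edges$target)), ids)
  if (length(unknown) > 0) {
    pn_stop(
      "pcanet_error_unknown_node",
      sprintf("edge list references unknown node id(s): %s",
              paste(utils::head(unknown, 5), collapse = ", "))
    )
  }
  if (any(edges$source == edges$target)) {
    pn_stop("pcanet_error_self_loop", "edge list contains self-loops")
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    pn_stop("pcanet_error_duplicate_edge", "edge list contains duplicate edges")
  }
  if (!allow_nonrespondent_edges) {
    resp <- stats::setNames(nodes$is_respondent, ids)
    nn <- !resp[edges$source] & !resp[edges$target]
    if (any(nn)) {
      pn_stop(
        "pcanet_error_nonrespondent_edge",
        sprintf(
          "%d edge(s) join two nonrespondents; such dyads are unobserved and cannot carry an edge in a partial network",
          sum(nn)
        )
      )
    }
  }
  invisible(TRUE)
}

new_pcanet_network <- function(nodes, edges, complete) {
  nodes$node_id <- as.character(nodes$node_id)
  nodes$is_respondent <- as.logical(nodes$is_respondent)
  if (anyNA(nodes$is_respondent)) {
    pn_stop("pcanet_error_bad_flag", "is_respondent must be TRUE/FALSE with no missing values")
  }
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  }
  edges <- canonical_edges(edges)
  validate_network_edges(nodes, edges, allow_nonrespondent_edges = complete)
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  nodes$soc_covariate <- compute_soc_covariate(nodes$node_id, nodes$is_respondent, edges)
  first <- c("node_id", "is_respondent", "soc_covariate")
  nodes <- nodes[, c(first, setdiff(names(nodes), first)), drop = FALSE]
  structure(
    list(nodes = nodes, edges = edges),
    class = c(if (complete) "complete_network" else "partial_network", "pcanet_network")
  )
}

#' Construct a partially observed undirected friendship network
#'
#' A partial network records the friendships observed for a set of survey
#' respondents: every respondent-respondent and respondent-nonrespondent
#' dyad is observed (present or absent), while every
#' nonrespondent-nonrespondent dyad is unobserved and carries no edge.
#'
#' @param nodes data frame with at least `node_id` (unique, coerced to
#'   character) and `is_respondent` (logical). Additional columns (e.g. age,
#'   city) are carried through untouched. A `soc_covariate` column, if
#'   present, is recomputed from the edge list: it always equals each node's
#'   observed number of respondent friends.
#' @param edges data frame with columns `source`, `target`; undirected, no
#'   self-loops or duplicates, and no edge may join two nonrespondents.
#' @return An object of class `partial_network` with elements `nodes` and
#'   `edges` (canonical form: `source < target`, rows sorted).
#' @export
partial_network <- function(nodes, edges = NULL) {
  new_pcanet_network(nodes, edges, complete = FALSE)
}

#' Construct a completed network
#'
#' A completed network additionally carries edges between nonrespondents
#' (for example imputed ones). The optional logical edge column `imputed`
#' flags edges that were filled in on formerly unobserved dyads.
#'
#' @inheritParams partial_network
#' @return An object of class `complete_network`.
#' @export
complete_network <- function(nodes, edges = NULL) {
  net <- new_pcanet_network(nodes, edges, complete = TRUE)
  if (!is.null(net$edges$imputed)) net$edges$imputed <- as.logical(net$edges$imputed)
  net
}

is_partial <- function(net) inherits(net, "partial_network")

n_nodes <- function(net) nrow(net$nodes)

respondent_flags <- function(net) {
  stats::setNames(net$nodes$is_respondent, net$nodes$node_id)
}

#' Classify dyads of a network as observed or unobserved
#'
#' @param net a `partial_network` or `complete_network`.
#' @param source,target character vectors of node ids (recycled pairwise).
#' @return character vector with values `"observed_present"`,
#'   `"observed_absent"` or `"unobserved"`. In a completed network no dyad
#'   is unobserved.
#' @export
dyad_status <- function(net, source, target) {
  source <- as.character(source)
  target <- as.character(target)
  flip <- source > target
  tmp <- source[flip]
  source[flip] <- target[flip]
  target[flip] <- tmp
  resp <- respondent_flags(net)
  if (anyNA(resp[source]) || anyNA(resp[target])) {
    pn_stop("pcanet_error_unknown_node", "dyad_status: unknown node id")
  }
  key <- paste(source, target, sep = "\r")
  present <- key %in% paste(net$edges$source, net$edges$target, sep = "\r")
  status <- ifelse(present, "observed_present", "observed_absent")
  if (is_partial(net)) {
    status[!resp[source] & !resp[target]] <- "unobserved"
  }
  status
}

#' Count dyads by observation status
#'
#' The three classes always conserve the total: `n_observed_present +
#' n_observed_absent + n_unobserved = choose(n, 2)`.
#'
#' @param net a `pcanet_network`.
#' @return named list of dyad counts.
#' @export
dyad_counts <- function(net) {
  n <- n_nodes(net)
  n_nonresp <- sum(!net$nodes$is_respondent)
  total <- choose(n, 2)
  unobserved <- if (is_partial(net)) choose(n_nonresp, 2) else 0
  present <- nrow(net$edges)
  list(
    n_dyads = total,
    n_observed_present = present,
    n_observed_absent = total - unobserved - present,
    n_unobserved = unobserved
  )
}

#' Read a network from node-table and edge-list CSV files
#'
#' The node table must contain columns `node_id` and `is_respondent`
#' (logical or 0/1); any further columns are carried along. The edge list
#' must contain `source` and `target`, and may contain a logical `imputed`
#' column, in which case a completed network is returned.
#'
#' Validation failures raise classed conditions:
#' `pcanet_error_unknown_node`, `pcanet_error_duplicate_edge`,
#' `pcanet_error_self_loop`, `pcanet_error_nonrespondent_edge`.
#'
#' @param node_table_path,edge_list_path paths to CSV files.
#' @return a `partial_network`, or a `complete_network` when the edge list
#'   carries an `imputed` column.
#' @seealso [write_network()]
#' @export
read_network <- function(node_table_path, edge_list_path) {
  for (p in c(node_table_path, edge_list_path)) {
    if (!file.exists(p)) {
      pn_stop("pcanet_error_missing_file", sprintf("input file not found: %s", p))
    }
  }
  nodes <- utils::read.csv(node_table_path, colClasses = c(node_id = "character"),
                           stringsAsFactors = FALSE)
  if (!all(c("node_id", "is_respondent") %in% names(nodes))) {
    pn_stop("pcanet_error_bad_header",
            "node table must have columns node_id, is_respondent")
  }
  nodes$is_respondent <- as.logical(nodes$is_respondent)
  edges <- utils::read.csv(edge_list_path,
                           colClasses = c(source = "character", target = "character"),
                           stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(edges))) {
    pn_stop("pcanet_error_bad_header", "edge list must have columns source, target")
  }
  if ("imputed" %in% names(edges)) {
    edges$imputed <- as.logical(edges$imputed)
    complete_network(nodes, edges)
  } else {
    partial_network(nodes, edges)
  }
}

#' Write a network to node-table and edge-list CSV files
#'
#' Lossless inverse of [read_network()]: node ids, respondent flags, extra
#' node columns, edges and (for completed networks) the `imputed` edge flag
#' round-trip unchanged. Rows are written in canonical order, so identical
#' networks produce byte-identical files.
#'
#' @param net a `pcanet_network`.
#' @param node_table_path,edge_list_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_network <- function(net, node_table_path, edge_list_path) {
  utils::write.csv(net$nodes, node_table_path, row.names = FALSE, quote = TRUE)
  utils::write.csv(net$edges, edge_list_path, row.names = FALSE, quote = TRUE)
  invisible(c(node_table_path, edge_list_path))
}

#' Convert a network to an igraph object
#'
#' Unobserved dyads of a partial network are treated as absent, i.e. the
#' graph contains exactly the present edges.
#'
#' @param net a `pcanet_network` (or an igraph object, returned as is).
#' @return an undirected igraph graph with vertex attributes `name` and
#'   `is_respondent`.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  stopifnot(inherits(net, "pcanet_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target"), drop = FALSE],
    directed = FALSE,
    vertices = net$nodes[, "node_id", drop = FALSE]
  )
  igraph::V(g)$is_respondent <- net$nodes$is_respondent
  g
}

#' Export a network as GraphML
#'
#' Completed networks keep the boolean `imputed` edge attribute (written as
#' 0/1), so imputed ties remain distinguishable from observed ones.
#'
#' @param net a `pcanet_network`.
#' @param path output file path.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  if (!is.null(net$edges$imputed)) {
    igraph::E(g)$imputed <- as.integer(net$edges$imputed)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Boundary specification for nonrespondent inclusion
#'
#' @param min_respondent_friends positive integer `k`: the minimum number of
#'   observed respondent friendships a nonrespondent needs to be retained.
#' @return an object of class `boundary_spec`.
#' @export
boundary_spec <- function(min_respondent_friends) {
  k <- as.integer(min_respondent_friends)
  if (length(k) != 1 || is.na(k) || k < 1) {
    pn_stop("pcanet_error_bad_boundary", "min_respondent_friends must be a single integer >= 1")
  }
  structure(list(min_respondent_friends = k), class = "boundary_spec")
}

#' Apply a degree-based boundary to a network
#'
#' Retains all respondents and exactly those nonrespondents with at least
#' `k` observed respondent friendships, dropping edges incident to removed
#' nodes. Sociability covariates are unchanged by construction: they count
#' friendships with respondents, none of whom are removed.
#'
#' @param net a `pcanet_network`.
#' @param spec a `boundary_spec`, or a single integer `k`.
#' @return a network of the same class restricted to the retained nodes. If
#'   no nonrespondent meets the threshold a `pcanet_warning_empty_boundary`
#'   warning is signalled and the respondent-only network is returned.
#' @export
apply_boundary <- function(net, spec) {
  if (!inherits(spec, "boundary_spec")) spec <- boundary_spec(spec)
  k <- spec$min_respondent_friends
  keep <- net$nodes$is_respondent | net$nodes$soc_covariate >= k
  if (!any(keep & !net$nodes$is_respondent)) {
    pn_warn("pcanet_warning_empty_boundary",
            sprintf("no nonrespondent has %d or more respondent friendships; retaining respondents only", k))
  }
  ids <- net$nodes$node_id[keep]
  old_soc <- stats::setNames(net$nodes$soc_covariate, net$nodes$node_id)[ids]
  edges <- net$edges[net$edges$source %in% ids & net$edges$target %in% ids, , drop = FALSE]
  out <- new_pcanet_network(net$nodes[keep, , drop = FALSE], edges, complete = !is_partial(net))
  stopifnot(identical(unname(old_soc), out$nodes$soc_covariate))
  out
}

#' Tabulate boundary specifications
#'
#' For each candidate threshold `k`, reports the share of respondents that
#' `k` represents, the number of nonrespondents retained, the number of
#' respondent-nonrespondent edges retained, and the number of unobserved
#' nonrespondent-nonrespondent dyads this implies (`choose(n_retained, 2)`).
#'
#' @param net a `partial_network`.
#' @param thresholds vector of positive integer thresholds.
#' @return data frame with one row per threshold: `k`,
#'   `pct_of_respondents` (rounded to one decimal),
#'   `n_nonresp_retained`, `edges_rn_retained`, `unobserved_dyads_nn`.
#' @export
boundary_table <- function(net, thresholds) {
  thresholds <- as.integer(thresholds)
  if (length(thresholds) == 0 || any(is.na(thresholds)) || any(thresholds < 1)) {
    pn_stop("pcanet_error_bad_boundary", "thresholds must be positive integers")
  }
  n_resp <- sum(net$nodes$is_respondent)
  soc_nr <- net$nodes$soc_covariate[!net$nodes$is_respondent]
  rows <- lapply(thresholds, function(k) {
    retained <- soc_nr[soc_nr >= k]
    data.frame(
      k = k,
      pct_of_respondents = round_half_up(100 * k / n_resp, 1),
      n_nonresp_retained = length(retained),
      ## each respondent-nonrespondent edge has exactly one nonrespondent
      ## endpoint, so retained RN edges = sum of retained sociabilities
      edges_rn_retained = sum(retained),
      unobserved_dyads_nn = choose(length(retained), 2)
    )
  })
  do.call(rbind, rows)
}

#' Quadrant metrics from raw counts
#'
#' Computes the densities and mean degrees implied by the four counts that
#' summarise a partially observed network: respondents, retained
#' nonrespondents, respondent-respondent (RR) edges, and
#' respondent-nonrespondent (RN) edges. This is the arithmetic core of
#' [quadrant_summary()] and can be applied directly to published counts.
#'
#' @param n_resp,n_nonresp node counts.
#' @param edges_rr,edges_rn edge counts by quadrant.
#' @return list with dyad counts, `density_rr` (= RR edges / choose(n_resp,
#'   2), `NA` when `n_resp < 2`), `density_rn` (= RN edges /
#'   (n_resp * n_nonresp)), `unobserved_dyads_nn`, and the four mean
#'   degrees: respondent total, respondent-respondent,
#'   respondent-nonrespondent, and nonrespondent observed.
#' @export
quadrant_metrics <- function(n_resp, n_nonresp, edges_rr, edges_rn) {
  dy_rr <- choose(n_resp, 2)
  dy_rn <- n_resp * n_nonresp
  structure(list(
    n_resp = n_resp,
    n_nonresp = n_nonresp,
    edges_rr = edges_rr,
    edges_rn = edges_rn,
    density_rr = if (n_resp < 2) NA_real_ else edges_rr / dy_rr,
    density_rn = if (dy_rn == 0) NA_real_ else edges_rn / dy_rn,
    unobserved_dyads_nn = choose(n_nonresp, 2),
    mean_degree_resp = if (n_resp > 0) (2 * edges_rr + edges_rn) / n_resp else NA_real_,
    mean_degree_resp_resp = if (n_resp > 0) 2 * edges_rr / n_resp else NA_real_,
    mean_degree_resp_nonresp = if (n_resp > 0) edges_rn / n_resp else NA_real_,
    mean_degree_nonresp_observed = if (n_nonresp > 0) edges_rn / n_nonresp else NA_real_
  ), class = "quadrant_summary")
}

#' Summarise the observed quadrants of a partial network
#'
#' Density is the ratio of observed friendships to the maximum possible
#' number in each quadrant; mean degrees are reported for respondents
#' (total, within-respondent, and with nonrespondents) and for the observed
#' degree of nonrespondents.
#'
#' @param net a `partial_network`.
#' @return a `quadrant_summary` (see [quadrant_metrics()]).
#' @export
quadrant_summary <- function(net) {
  resp <- respondent_flags(net)
  src_r <- resp[net$edges$source]
  tgt_r <- resp[net$edges$target]
  quadrant_metrics(
    n_resp = sum(net$nodes$is_respondent),
    n_nonresp = sum(!net$nodes$is_respondent),
    edges_rr = sum(src_r & tgt_r),
    edges_rn = sum(xor(src_r, tgt_r))
  )
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat(sprintf("Quadrant summary: %d respondents, %d nonrespondents\n",
              x$n_resp, x$n_nonresp))
  cat(sprintf("  RR edges %d (density %s), RN edges %d (density %s)\n",
              x$edges_rr, format_pct(x$density_rr), x$edges_rn, format_pct(x$density_rn)))
  cat(sprintf("  unobserved NN dyads: %.0f\n", x$unobserved_dyads_nn))
  cat(sprintf("  mean degrees: respondent %.1f (RR %.1f, RN %.1f), nonrespondent observed %.1f\n",
              x$mean_degree_resp, x$mean_degree_resp_resp,
              x$mean_degree_resp_nonresp, x$mean_degree_nonresp_observed))
  invisible(x)
}

#' Binned degree distribution
#'
#' Degrees are computed over all present edges (imputed edges included when
#' given a completed network) and binned into half-open intervals
#' `[b, b + bin_width)`.
#'
#' @param net a `pcanet_network`.
#' @param role `"respondent"` or `"nonrespondent"`.
#' @param bin_width positive integer bin width (default 10).
#' @return data frame with columns `bin_lo`, `bin_hi`, `count`; counts sum
#'   to the number of nodes of the requested role.
#' @export
degree_distribution <- function(net, role = c("respondent", "nonrespondent"),
                                bin_width = 10L) {
  role <- match.arg(role)
  bin_width <- as.integer(bin_width)
  stopifnot(bin_width >= 1)
  want <- if (role == "respondent") net$nodes$is_respondent else !net$nodes$is_respondent
  ends <- c(net$edges$source, net$edges$target)
  deg <- table(factor(ends, levels = net$nodes$node_id))
  deg <- as.integer(deg)[want]
  if (length(deg) == 0) {
    return(data.frame(bin_lo = integer(0), bin_hi = integer(0), count = integer(0)))
  }
  bin <- deg %/% bin_width
  bins <- 0:max(bin)
  data.frame(
    bin_lo = bins * bin_width,
    bin_hi = (bins + 1L) * bin_width,
    count = as.integer(table(factor(bin, levels = bins)))
  )
}

#' @export
print.partial_network <- function(x, ...) {
  dc <- dyad_counts(x)
  cat(sprintf(
    "partial_network: %d nodes (%d respondents), %d observed edges\n",
    n_nodes(x), sum(x$nodes$is_respondent), nrow(x$edges)))
  cat(sprintf("  dyads: %.0f present / %.0f absent / %.0f unobserved\n",
              dc$n_observed_present, dc$n_observed_absent, dc$n_unobserved))
  invisible(x)
}

#' @export
print.complete_network <- function(x, ...) {
  n_imp <- if (is.null(x$edges$imputed)) 0L else sum(x$edges$imputed)
  cat(sprintf("complete_network: %d nodes (%d respondents), %d edges (%d imputed)\n",
              n_nodes(x), sum(x$nodes$is_respondent), nrow(x$edges), n_imp))
  invisible(x)
}

## round-half-away-from-zero at `digits` decimals, matching the reporting
## convention used for printed percentages (base round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

format_pct <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f%%"), round_half_up(100 * x, digits)))
}
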