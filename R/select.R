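#' Selection configuration for peer change agent identification
#'
#' @param m target set size; the study convention is 300, roughly 8% of the
#'   estimated target population.
#' @param algorithm `"eigenvector"` or `"keyplayer"`.
#' @param kp_restarts number of seeded hill-climbing restarts for keyplayer
#'   (the first start is always the greedy seeding).
#' @param kp_max_sweeps swap-improvement sweeps per restart.
#' @param seed integer seed controlling keyplayer's stochastic swaps.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(m = 300, algorithm = c("eigenvector", "keyplayer"),
                             kp_restarts = 1, kp_max_sweeps = 10, seed = 1) {
  algorithm <- match.arg(algorithm)
  m <- as.integer(m)
  if (is.na(m) || m < 1) pn_stop("pcanet_error_bad_config", "m must be a positive integer")
  structure(list(m = m, algorithm = algorithm,
                 kp_restarts = as.integer(kp_restarts),
                 kp_max_sweeps = as.integer(kp_max_sweeps),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Eigenvector centrality scores
#'
#' Principal eigenvector of the adjacency matrix, computed by power
#' iteration from a deterministic uniform start vector, with the iteration
#' run on `A + I` (same eigenvector, and the shift rules out oscillation on
#' bipartite graphs). Scores are nonnegative and normalised to unit
#' Euclidean length; nodes outside the dominant component receive scores
#' numerically indistinguishable from 0.
#'
#' @param net a `pcanet_network` or igraph graph (simple, undirected).
#'   Unobserved dyads of a partial network are treated as absent.
#' @param tol relative-change stopping tolerance (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @return named numeric vector of scores, one per node.
#' @export
eigenvector_scores <- function(net, tol = 1e-10, max_iter = 10000) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0) pn_stop("pcanet_error_empty_graph", "eigenvector centrality of an empty graph")
  ids <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x
    y <- y / sqrt(sum(y^2))
    if (sqrt(sum((y - x)^2)) < tol) {
      x <- y
      break
    }
    x <- y
  }
  stats::setNames(x, ids)
}

#' Top-m nodes by score
#'
#' Ties at the selection boundary are broken by lexicographic node id, so
#' selection is deterministic.
#'
#' @param scores named numeric vector.
#' @param m number of nodes to select (`m <= length(scores)`).
#' @return character vector of `m` node ids, sorted lexicographically.
#' @export
top_m <- function(scores, m) {
  m <- as.integer(m)
  if (m > length(scores)) {
    pn_stop("pcanet_error_bad_config", "m exceeds the number of nodes")
  }
  ord <- order(-scores, names(scores))
  sort(names(scores)[ord[seq_len(m)]])
}

## Shortest-path distance matrix with Inf for unreachable pairs.
distance_matrix <- function(net) {
  g <- as_igraph(net)
  D <- igraph::distances(g, weights = NA)
  dimnames(D) <- list(igraph::V(g)$name, igraph::V(g)$name)
  D
}

kpp_fitness_from_D <- function(D, S_idx) {
  n <- nrow(D)
  d <- if (length(S_idx) == 1) D[S_idx, ] else apply(D[S_idx, , drop = FALSE], 2, min)
  outside <- setdiff(seq_len(n), S_idx)
  sum(1 / d[outside][is.finite(d[outside]) & d[outside] > 0]) / n
}

#' Keyplayer-positive fitness (distance-weighted reach)
#'
#' Borgatti's KPP-Pos criterion: `D_R(S) = (sum over j not in S of
#' 1 / d(S, j)) / n`, where `d(S, j)` is the shortest-path distance from
#' `j` to the nearest member of `S` and `1 / Inf = 0` for unreachable
#' nodes. Members are excluded from the summation but included in the
#' normalising `n`, so `D_R` lies in `[0, 1]` and equals 1 only when every
#' non-member is adjacent to the set.
#'
#' @param net a `pcanet_network` or igraph graph.
#' @param S nonempty character vector of member node ids.
#' @return fitness value in `[0, 1]`.
#' @export
kpp_fitness <- function(net, S) {
  if (length(S) == 0) pn_stop("pcanet_error_empty_set", "keyplayer fitness of an empty set")
  D <- distance_matrix(net)
  idx <- match(S, rownames(D))
  if (anyNA(idx)) pn_stop("pcanet_error_unknown_node", "set member not found in network")
  kpp_fitness_from_D(D, idx)
}

## Greedy seeding: iteratively add the node with the largest fitness gain.
## Exact, but incremental: writing iv = 1/d (0 for unreachable), the
## candidate objective decomposes as
##   n * F(S + v) = sum_{j outside} max(ivmin_j, IV[v, j]) - ivmin_v
##                = B + g_v - ivmin_v,
## where ivmin_j = iv(d(S, j)) and g_v = sum_j max(IV[v, j] - ivmin_j, 0)
## accumulates v's improvements over the current reach. Adding a member
## only changes the columns it improves, so g is updated column-wise
## rather than recomputed, which keeps study-scale greedy fast.
kpp_greedy <- function(D, m) {
  n <- nrow(D)
  ids <- rownames(D)
  IV <- 1 / D
  IV[!is.finite(IV)] <- 0          # diagonal (d=0) and unreachable (d=Inf)
  ivmin <- numeric(n)              # iv of d(S, j); 0 while S is empty
  g <- rowSums(IV)
  in_S <- rep(FALSE, n)
  S <- integer(0)
  for (step in seq_len(m)) {
    score <- g - ivmin
    score[in_S] <- -Inf
    best <- which(score == max(score))
    w <- best[order(ids[best])][1]         # lexicographic tie-break
    old_ivmin <- ivmin
    new_ivmin <- pmax(ivmin, IV[w, ])
    in_S[w] <- TRUE
    S <- c(S, w)
    ## w's column leaves the outside sum entirely
    g <- g - pmax(IV[, w] - old_ivmin[w], 0)
    improved <- which(new_ivmin > old_ivmin & !in_S)
    for (j in improved) {
      g <- g + pmax(IV[, j] - new_ivmin[j], 0) - pmax(IV[, j] - old_ivmin[j], 0)
    }
    ivmin <- new_ivmin
  }
  S
}

## Swap hill-climbing over member<->nonmember exchanges. On small graphs
## (n <= scan_limit) each sweep scans the full swap neighbourhood and takes
## the best improving exchange (steepest ascent); on larger graphs each
## sweep makes |S| random proposals and accepts improvements, which keeps
## the cost linear in n per proposal.
kpp_swap_improve <- function(D, S, max_sweeps, n_total, scan_limit = 100) {
  n <- nrow(D)
  inv <- function(x) ifelse(is.finite(x) & x > 0, 1 / x, 0)
  current <- kpp_fitness_from_D(D, S)
  if (length(S) >= n || max_sweeps < 1) return(list(S = S, fitness = current))
  ## two smallest distances to S per column, for O(n) member-removal updates
  two_smallest <- function(S_idx) {
    Ds <- D[S_idx, , drop = FALSE]
    neg <- -Ds
    neg[!is.finite(neg)] <- -.Machine$double.xmax
    a1 <- max.col(t(neg), ties.method = "first")   # per-column argmin row
    d1 <- Ds[cbind(a1, seq_len(n))]
    if (nrow(Ds) == 1) {
      d2 <- rep(Inf, n)
    } else {
      Ds2 <- Ds
      Ds2[cbind(a1, seq_len(n))] <- Inf
      d2 <- do.call(pmin, lapply(seq_len(nrow(Ds2)), function(r) Ds2[r, ]))
    }
    list(d1 = d1, d2 = d2, who = S_idx[a1])
  }
  ts <- two_smallest(S)
  swap_fitness <- function(u, v) {
    d_wo_u <- ifelse(ts$who == u, ts$d2, ts$d1)
    d_new <- pmin(d_wo_u, D[v, ])
    w <- inv(d_new)
    w[c(setdiff(S, u), v)] <- 0
    sum(w) / n
  }
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    if (n <= scan_limit) {
      best <- list(fit = current, u = NA, v = NA)
      out <- setdiff(seq_len(n), S)
      for (u in S) {
        for (v in out) {
          f <- swap_fitness(u, v)
          if (f > best$fit + 1e-15) best <- list(fit = f, u = u, v = v)
        }
      }
      if (!is.na(best$u)) {
        S <- c(setdiff(S, best$u), best$v)
        current <- best$fit
        ts <- two_smallest(S)
        improved <- TRUE
      }
    } else {
      for (prop in seq_along(S)) {
        u <- S[sample.int(length(S), 1)]
        out <- setdiff(seq_len(n), S)
        v <- out[sample.int(length(out), 1)]
        f <- swap_fitness(u, v)
        if (f > current + 1e-15) {
          S <- c(setdiff(S, u), v)
          current <- f
          ts <- two_smallest(S)
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(S = S, fitness = current)
}

#' Select a keyplayer-positive set
#'
#' Greedy seeding (iteratively adding the node that maximises the fitness
#' gain) followed by stochastic swap hill-climbing; with `kp_restarts > 1`,
#' additional restarts begin from random seed sets, and the best set found
#' across restarts is returned. The result never has lower fitness than the
#' pure greedy seeding, and is deterministic given `seed`.
#'
#' @param net a `pcanet_network` or igraph graph.
#' @param m set size.
#' @param kp_restarts number of restarts (first is greedy).
#' @param kp_max_sweeps swap sweeps per restart.
#' @param seed integer seed.
#' @return character vector of `m` node ids, sorted lexicographically.
#' @export
kpp_select <- function(net, m, kp_restarts = 1, kp_max_sweeps = 10, seed = 1) {
  D <- distance_matrix(net)
  n <- nrow(D)
  m <- as.integer(m)
  if (m > n) pn_stop("pcanet_error_bad_config", "m exceeds the number of nodes")
  if (m == n) return(sort(rownames(D)))
  set.seed(seed)
  greedy <- kpp_greedy(D, m)
  best <- kpp_swap_improve(D, greedy, kp_max_sweeps, n)
  if (best$fitness < kpp_fitness_from_D(D, greedy)) {
    best <- list(S = greedy, fitness = kpp_fitness_from_D(D, greedy))
  }
  if (kp_restarts > 1) {
    for (r in seq_len(kp_restarts - 1)) {
      start <- sample.int(n, m)
      cand <- kpp_swap_improve(D, start, kp_max_sweeps, n)
      if (cand$fitness > best$fitness + 1e-15) best <- cand
    }
  }
  sort(rownames(D)[best$S])
}

select_on_network <- function(net, config, seed_offset = 0) {
  if (config$algorithm == "eigenvector") {
    top_m(eigenvector_scores(net), config$m)
  } else {
    kpp_select(net, config$m,
               kp_restarts = config$kp_restarts,
               kp_max_sweeps = config$kp_max_sweeps,
               seed = config$seed + seed_offset)
  }
}

#' Selection counts across an ensemble of completed networks
#'
#' Applies the configured algorithm to every ensemble member and counts,
#' for each node, the number of networks on which it entered the size-m
#' selected set. Nodes never selected are absent from the result.
#'
#' @param ensemble an `imputed_ensemble` or a list of networks.
#' @param config a [selection_config()]. Keyplayer runs on member `i` use
#'   seed `config$seed + i` so the ensemble is reproducible member-by-member.
#' @return named integer vector of counts with attribute `M`.
#' @export
aggregate_selections <- function(ensemble, config) {
  nets <- if (inherits(ensemble, "imputed_ensemble")) ensemble_networks(ensemble) else ensemble
  if (length(nets) == 0) pn_stop("pcanet_error_bad_config", "ensemble is empty")
  sel <- lapply(seq_along(nets), function(i) select_on_network(nets[[i]], config, seed_offset = i))
  tab <- table(unlist(sel, use.names = FALSE))
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts <- counts[order(names(counts))]
  attr(counts, "M") <- length(nets)
  counts
}

#' Sufficiency cutoff and sPCA set
#'
#' Scans integer thresholds `t` from `M` down to 1 and, writing `s(t)` for
#' the number of nodes selected on at least `t` networks, chooses the `t`
#' minimising `|s(t) - m_target|`; ties go to the larger `t` (the smaller
#' set), matching the rule "the smallest PCA set closest in size to the
#' target". PCAs meeting the cutoff form the sPCA set.
#'
#' @param counts named selection counts (see [aggregate_selections()]).
#' @param m_target desired set size.
#' @param M number of networks in the ensemble; defaults to the `M`
#'   attribute of `counts`, falling back to `max(counts)`.
#' @return list with `cutoff` (integer) and `spca_set` (sorted ids).
#' @export
sufficiency_cutoff <- function(counts, m_target, M = NULL) {
  if (length(counts) == 0) pn_stop("pcanet_error_bad_config", "counts is empty")
  if (is.null(M)) M <- attr(counts, "M")
  if (is.null(M)) M <- max(counts)
  best_t <- NA_integer_
  best_gap <- Inf
  for (t in seq(M, 1)) {
    gap <- abs(sum(counts >= t) - m_target)
    if (gap < best_gap) {        # ties keep the earlier (larger) t
      best_gap <- gap
      best_t <- t
    }
  }
  list(cutoff = best_t, spca_set = sort(names(counts)[counts >= best_t]))
}

set_composition <- function(ids, flags) {
  n_resp <- sum(flags[ids])
  list(n = length(ids), n_respondent = n_resp,
       n_nonrespondent = length(ids) - n_resp,
       pct_nonrespondent = if (length(ids) > 0)
         round_half_up(100 * (length(ids) - n_resp) / length(ids), 1) else NA_real_)
}

#' Identify peer change agents on the observed network and an ensemble
#'
#' Computes the size-m PCA set on the observed network (unobserved dyads
#' treated as absent), the per-node selection counts across the imputed
#' ensemble, and the sPCA set implied by the sufficiency cutoff.
#'
#' @param partial_net the observed `partial_network`.
#' @param ensemble an `imputed_ensemble` (or list of completed networks)
#'   over the same node set.
#' @param config a [selection_config()].
#' @return an object of class `selection_result` with fields `algorithm`,
#'   `m`, `observed_set`, `counts`, `cutoff`, `spca_set` and
#'   respondent/nonrespondent `composition` of both sets.
#' @export
select_pcas <- function(partial_net, ensemble, config) {
  nets <- if (inherits(ensemble, "imputed_ensemble")) ensemble_networks(ensemble) else ensemble
  same <- vapply(nets, function(nw) identical(nw$nodes$node_id, partial_net$nodes$node_id),
                 logical(1))
  if (!all(same)) {
    pn_stop("pcanet_error_node_mismatch",
            "ensemble networks and observed network have different node sets")
  }
  observed_set <- select_on_network(partial_net, config, seed_offset = 0)
  counts <- aggregate_selections(nets, config)
  cut <- sufficiency_cutoff(counts, config$m)
  flags <- respondent_flags(partial_net)
  structure(list(
    algorithm = config$algorithm,
    m = config$m,
    seed = config$seed,
    M = length(nets),
    observed_set = observed_set,
    counts = counts,
    cutoff = cut$cutoff,
    spca_set = cut$spca_set,
    composition = list(
      observed = set_composition(observed_set, flags),
      spca = set_composition(cut$spca_set, flags)
    )
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s, m = %d, M = %d)\n", x$algorithm, x$m, x$M))
  cat(sprintf("  observed PCAs: %d (%.1f%% nonrespondent)\n",
              length(x$observed_set), x$composition$observed$pct_nonrespondent))
  cat(sprintf("  sufficiency cutoff: selected on >= %d networks -> %d sPCAs (%.1f%% nonrespondent)\n",
              x$cutoff, length(x$spca_set), x$composition$spca$pct_nonrespondent))
  invisible(x)
}

#' Serialise a selection result to JSON
#'
#' @param x a `selection_result`.
#' @param path output path.
#' @export
write_selection <- function(x, path) {
  out <- list(
    algorithm = x$algorithm, m = x$m, seed = x$seed, M = x$M,
    observed_set = x$observed_set,
    counts = as.list(stats::setNames(as.integer(x$counts), names(x$counts))),
    cutoff = x$cutoff, spca_set = x$spca_set,
    composition = x$composition
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a serialised selection result
#'
#' @param path path written by [write_selection()].
#' @return a `selection_result`.
#' @export
read_selection <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- stats::setNames(as.integer(unlist(raw$counts)), names(raw$counts))
  attr(counts, "M") <- raw$M
  structure(list(
    algorithm = raw$algorithm, m = as.integer(raw$m), seed = as.integer(raw$seed),
    M = as.integer(raw$M),
    observed_set = as.character(raw$observed_set),
    counts = counts,
    cutoff = as.integer(raw$cutoff),
    spca_set = as.character(raw$spca_set),
    composition = raw$composition
  ), class = "selection_result")
}
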