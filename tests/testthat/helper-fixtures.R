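# Fixture builders and independent oracles shared across the suite.
# Oracles deliberately avoid the code paths they check: shortest paths are
# recomputed with a hand-written BFS rather than igraph, eigenvectors with
# a dense eigendecomposition rather than power iteration.

toy_nodes <- function() {
  data.frame(
    node_id = c("A", "B", "C", "D"),
    is_respondent = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Random valid partial network built directly from Bernoulli quadrants,
# independent of the package's synthetic generator.
random_partial <- function(seed, n_resp = 6, n_nonresp = 8, p_rr = 0.4, p_rn = 0.3) {
  set.seed(seed)
  ids_r <- sprintf("r%02d", seq_len(n_resp))
  ids_n <- sprintf("x%02d", seq_len(n_nonresp))
  edges <- list()
  for (i in seq_len(n_resp)) {
    for (j in seq_len(n_resp)) {
      if (i < j && runif(1) < p_rr) edges[[length(edges) + 1]] <- c(ids_r[i], ids_r[j])
    }
    for (j in seq_len(n_nonresp)) {
      if (runif(1) < p_rn) edges[[length(edges) + 1]] <- c(ids_r[i], ids_n[j])
    }
  }
  em <- do.call(rbind, edges)
  edf <- if (is.null(em)) NULL else data.frame(source = em[, 1], target = em[, 2],
                                               stringsAsFactors = FALSE)
  partial_network(
    data.frame(node_id = c(ids_r, ids_n),
               is_respondent = rep(c(TRUE, FALSE), c(n_resp, n_nonresp)),
               stringsAsFactors = FALSE),
    edf
  )
}

star_graph <- function(n_leaves = 4, center = "c0", leaf_prefix = "l") {
  leaves <- sprintf("%s%02d", leaf_prefix, seq_len(n_leaves))
  igraph::graph_from_data_frame(
    data.frame(source = center, target = leaves), directed = FALSE)
}

# Connected Erdos-Renyi graph with named vertices (resampled until connected).
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}

# --- independent oracles ------------------------------------------------

# BFS all-pairs distances from an edge matrix of 1-based integer indices.
bfs_dist_matrix <- function(edge_idx, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edge_idx))) {
    i <- edge_idx[r, 1]; j <- edge_idx[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

graph_edge_idx <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  matrix(as.integer(el), ncol = 2)
}

# Distance-weighted reach computed from an oracle distance matrix.
oracle_kpp_fitness <- function(D, S_idx) {
  n <- nrow(D)
  out <- setdiff(seq_len(n), S_idx)
  total <- 0
  for (j in out) {
    dj <- min(D[S_idx, j])
    if (is.finite(dj) && dj > 0) total <- total + 1 / dj
  }
  total / n
}

# Principal eigenvector via dense eigendecomposition (sign-fixed, unit norm).
oracle_eigenvector <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  if (sum(v) < 0) v <- -v
  stats::setNames(v / sqrt(sum(v^2)), igraph::V(g)$name)
}

skewness <- function(x) mean(((x - mean(x)) / stats::sd(x))^3)
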