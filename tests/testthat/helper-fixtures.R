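# Fixture builders shared across test files.

# Wrap a symmetric zero-diagonal weight matrix as a connectivity_matrix.
make_cm <- function(W, method = "CORR", labels = NULL) {
  labels <- labels %||% paste0("Ch", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  structure(list(weights = W, method = method, band = NULL,
                 channel_labels = labels),
            class = "connectivity_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sym_from_edges <- function(n, edges) {
  W <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    W[edges[r, 1], edges[r, 2]] <- edges[r, 3]
    W[edges[r, 2], edges[r, 1]] <- edges[r, 3]
  }
  W
}

# A 16-node, 100-edge weight matrix whose exact edge-removal disconnection
# point on a 1% grid is p_disc: nodes 1..15 carry a high-weight spanning
# path plus filler edges; node 16 hangs on a single bridge whose ascending
# rank is exactly 100 * p_disc.
make_disconnect_matrix <- function(p_disc) {
  k_star <- round(100 * p_disc)
  stopifnot(k_star >= 15, k_star <= 86)
  pairs <- t(combn(15, 2))
  path <- cbind(1:14, 2:15)
  is_path <- paste(pairs[, 1], pairs[, 2]) %in% paste(path[, 1], path[, 2])
  filler <- pairs[!is_path, , drop = FALSE]
  n_low <- k_star - 1
  n_extra <- 100 - k_star - 14
  edges <- rbind(
    cbind(filler[seq_len(n_low), , drop = FALSE], rank = seq_len(n_low)),
    cbind(1, 16, rank = k_star),
    cbind(path, rank = k_star + 1:14),
    cbind(filler[n_low + seq_len(n_extra), , drop = FALSE],
          rank = k_star + 14 + seq_len(n_extra))
  )
  make_cm(sym_from_edges(16, cbind(edges[, 1:2], edges[, 3] / 101)))
}

# Random connected weighted graph on n nodes: a random spanning tree plus
# extra random edges, weights U(0,1).
random_connected_matrix <- function(n, extra = n) {
  repeat {
    W <- matrix(0, n, n)
    perm <- sample(n)
    for (i in 2:n) {
      j <- perm[sample(i - 1, 1)]
      W[perm[i], j] <- W[j, perm[i]] <- runif(1)
    }
    for (e in seq_len(extra)) {
      ij <- sample(n, 2)
      W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- runif(1)
    }
    if (oracle_connected(W)) return(W)
  }
}

# Ring lattice on n nodes, each joined to k/2 neighbours on each side, with
# a couple of deterministic long-range rewirings (small-world construction).
make_rewired_lattice <- function(n = 19, k = 4, rewire = 2) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in seq_len(k / 2)) {
    j <- ((i - 1 + d) %% n) + 1
    W[i, j] <- W[j, i] <- 1
  }
  for (r in seq_len(rewire)) {
    i <- r; j <- ((i - 1 + 1) %% n) + 1        # remove a nearest edge
    W[i, j] <- W[j, i] <- 0
    far <- ((i - 1 + floor(n / 2)) %% n) + 1   # add a chord
    W[i, far] <- W[far, i] <- 1
  }
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
}

# Tiny cohort for pipeline-level tests.
quick_cohort_config <- function(...) {
  cohort_config(n_per_group = 3, n_channels = 6, fs = 100, duration = 12,
                coupling_pc = 0.2, coupling_pe = 0.7, noise_sd = 0.5,
                seed = 99, ...)
}
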