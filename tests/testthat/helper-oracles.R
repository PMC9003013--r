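# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (naive DFT sums, BFS, Floyd-Warshall).

# Coherency by explicit per-segment DFT sums, hand-averaged.
oracle_coherency <- function(x, y, fs, segment_len = 1, overlap = 0.5) {
  L <- round(segment_len * fs)
  step <- round(L * (1 - overlap))
  nseg <- floor((length(x) - L) / step) + 1
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  nf <- floor(L / 2) + 1
  Sxx <- numeric(nf); Syy <- numeric(nf)
  Sxy <- complex(length.out = nf)
  tt <- 0:(L - 1)
  for (s in seq_len(nseg)) {
    i0 <- (s - 1) * step
    xs <- x[(i0 + 1):(i0 + L)] * w
    ys <- y[(i0 + 1):(i0 + L)] * w
    for (f in seq_len(nf)) {
      e <- exp(-2i * pi * (f - 1) * tt / L)
      X <- sum(xs * e); Y <- sum(ys * e)
      Sxx[f] <- Sxx[f] + Mod(X)^2
      Syy[f] <- Syy[f] + Mod(Y)^2
      Sxy[f] <- Sxy[f] + X * Conj(Y)
    }
  }
  list(freq = (0:(nf - 1)) * fs / L, K = Sxy / sqrt(Sxx * Syy))
}

oracle_msc <- function(x, y, fs, band_low, band_high, segment_len = 1, overlap = 0.5) {
  oc <- oracle_coherency(x, y, fs, segment_len, overlap)
  keep <- oc$freq >= band_low & oc$freq <= band_high
  mean(Mod(oc$K[keep])^2)
}

# BFS connectivity of an adjacency (or weight) matrix.
oracle_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(A[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Floyd-Warshall all-pairs shortest paths; `lengths` is a matrix of edge
# lengths (Inf where no edge).
oracle_apsp <- function(lengths) {
  D <- lengths
  diag(D) <- 0
  n <- nrow(D)
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Hop-count and weighted path summaries of a weight matrix, for comparison
# with avg_path_length() / weighted_diameter() on the same graph.
oracle_path_metrics <- function(W) {
  hop <- ifelse(W > 0, 1, Inf)
  Dh <- oracle_apsp(hop)
  wl <- ifelse(W > 0, W, Inf)
  Dw <- oracle_apsp(wl)
  pairs_h <- Dh[upper.tri(Dh)]
  pairs_w <- Dw[upper.tri(Dw)]
  list(apl = mean(pairs_h[is.finite(pairs_h)]),
       diam = if (any(is.finite(pairs_w))) max(pairs_w[is.finite(pairs_w)]) else 0)
}

# Exhaustive disconnect point: test every grid value independently with BFS.
oracle_disconnect_point <- function(W, step = 0.01) {
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ord <- order(W[idx], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  E <- nrow(idx)
  for (p in seq(0, 1, by = step)) {
    k <- floor(p * E + 1e-9)
    A <- W
    if (k > 0) for (r in seq_len(k)) {
      A[idx[r, 1], idx[r, 2]] <- 0
      A[idx[r, 2], idx[r, 1]] <- 0
    }
    if (!oracle_connected(A)) return(p)
  }
  1
}
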