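#' Spectral estimation parameters
#'
#' Parameters of the Welch averaged-periodogram estimator behind the
#' coherence-based measures: tapered segments of `segment_len` seconds with
#' fractional overlap `overlap_frac`. The defaults (1 s Hann segments, 50%
#' overlap) are the only well-conditioned choice inside 3 s sliding windows.
#'
#' @param segment_len Segment length in seconds.
#' @param overlap_frac Overlap fraction in \[0, 1).
#' @param taper Taper name; currently `"hann"` or `"rect"`.
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(segment_len = 1, overlap_frac = 0.5, taper = "hann") {
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must lie in [0, 1)")
  if (!taper %in% c("hann", "rect")) stop("unknown taper '", taper, "'")
  structure(list(segment_len = segment_len, overlap_frac = overlap_frac,
                 taper = taper), class = "spectral_params")
}

# Welch cross-spectral matrices for a channels x samples matrix.
# Returns freq (one-sided) and S, an nf x nch x nch complex array with
# S[f, i, j] = mean over segments of Z_i(f) * Conj(Z_j(f)).
welch_csd <- function(X, fs, sp) {
  nch <- nrow(X); n <- ncol(X)
  L <- round(sp$segment_len * fs)
  if (L < 32) stop("segment_len * fs must be at least 32 samples; got ", L)
  if (n < L) stop("signal too short (", n, " samples) for ", L, "-sample segments")
  step <- max(1, round(L * (1 - sp$overlap_frac)))
  nseg <- floor((n - L) / step) + 1
  w <- if (sp$taper == "hann") hann_window(L) else rep(1, L)
  starts <- (seq_len(nseg) - 1) * step
  M <- matrix(0, L, nseg * nch)
  for (ch in seq_len(nch))
    for (s in seq_len(nseg))
      M[, (ch - 1) * nseg + s] <- X[ch, (starts[s] + 1):(starts[s] + L)] * w
  Z <- mvfft(M)
  nf <- floor(L / 2) + 1
  S <- array(0i, c(nf, nch, nch))
  for (f in seq_len(nf)) {
    Zf <- matrix(Z[f, ], nrow = nseg)            # nseg x nch
    S[f, , ] <- (t(Zf) %*% Conj(Zf)) / nseg
  }
  list(freq = (0:(nf - 1)) * fs / L, S = S)
}

band_bins <- function(freq, band) {
  idx <- which(freq >= band$low & freq <= band$high)
  if (!length(idx))
    stop("no frequency bins inside band [", band$low, ", ", band$high,
         "] Hz at this resolution")
  idx
}

#' Coherency spectrum of two signals
#'
#' The complex coherency `K_xy(f) = S_xy / sqrt(S_xx S_yy)` from Welch
#' averaged periodograms. [msc()] and [icoh()] are band summaries of this
#' spectrum.
#'
#' @param x,y Equal-length numeric signals.
#' @param fs Sampling rate in Hz.
#' @param sp [spectral_params()].
#' @return List with `freq` and complex `coherency`.
#' @export
coherency_spectrum <- function(x, y, fs, sp = spectral_params()) {
  if (length(x) != length(y))
    stop("signals differ in length (", length(x), " vs ", length(y), ")")
  cs <- welch_csd(rbind(x, y), fs, sp)
  sxx <- Re(cs$S[, 1, 1]); syy <- Re(cs$S[, 2, 2])
  K <- cs$S[, 1, 2] / sqrt(pmax(sxx * syy, .Machine$double.xmin))
  list(freq = cs$freq, coherency = K)
}

#' Magnitude-squared coherence
#'
#' Mean over the in-band frequency bins of `|K_xy(f)|^2`, the squared modulus
#' of the normalized cross-spectrum. 1 means perfect linear dependence at
#' every in-band frequency; 0 means none.
#'
#' @inheritParams coherency_spectrum
#' @param band A [band_spec()].
#' @return A weight in \[0, 1\].
#' @examples
#' x <- rnorm(1000)
#' msc(x, x, fs = 100, band = band_spec("Full", 0.5, 45))  # == 1
#' @export
msc <- function(x, y, fs, band, sp = spectral_params()) {
  ks <- coherency_spectrum(x, y, fs, sp)
  m <- mean(Mod(ks$coherency[band_bins(ks$freq, band)])^2)
  min(max(m, 0), 1)
}

#' Imaginary part of coherency
#'
#' Mean over the in-band bins of `|Im K_xy(f)|`. Insensitive by construction
#' to zero-lag (instantaneous) mixing, hence robust to volume conduction:
#' any scaled copy of a signal has purely real coherency with it.
#'
#' @inheritParams msc
#' @return A weight in \[0, 1\].
#' @export
icoh <- function(x, y, fs, band, sp = spectral_params()) {
  ks <- coherency_spectrum(x, y, fs, sp)
  m <- mean(abs(Im(ks$coherency[band_bins(ks$freq, band)])))
  min(max(m, 0), 1)
}

#' Phase lag index
#'
#' Instantaneous phases come from the analytic signal (Hilbert transform);
#' the phase difference is wrapped to (-pi, pi\] and
#' `PLI = |mean(sign(delta_phi))|`. Signed differences are used, so
#' consistent leads and lags are detected while zero-lag coupling maps to 0.
#' The first and last `trim_frac` of samples are discarded before averaging
#' to avoid Hilbert boundary distortion. Inputs are expected to be already
#' band-limited; no filtering happens here.
#'
#' @param x,y Equal-length, band-limited numeric signals.
#' @param trim_frac Fraction of samples trimmed from each end (default 0.1).
#' @return A weight in \[0, 1\]; 1 is complete phase locking at a consistent
#'   nonzero lag.
#' @export
pli <- function(x, y, trim_frac = 0.1) {
  if (length(x) != length(y))
    stop("signals differ in length (", length(x), " vs ", length(y), ")")
  px <- Arg(analytic_signal(x))
  py <- Arg(analytic_signal(y))
  idx <- pli_keep_idx(length(x), trim_frac)
  d <- wrap_phase(px[idx] - py[idx])
  min(abs(mean(sign(d))), 1)
}

pli_keep_idx <- function(n, trim_frac) {
  tr <- floor(n * trim_frac)
  (tr + 1):(n - tr)
}

#' Absolute Pearson correlation
#'
#' `|r|` between two signals; the absolute value is taken because network
#' edge weights must be nonnegative.
#'
#' @param x,y Equal-length numeric signals with nonzero variance.
#' @return A weight in \[0, 1\].
#' @export
pearson_abs <- function(x, y) {
  if (length(x) != length(y))
    stop("signals differ in length (", length(x), " vs ", length(y), ")")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  min(abs(cor(x, y)), 1)
}

conn_methods <- c("MSC", "iCOH", "PLI", "CORR")

#' Channel-by-channel connectivity matrix
#'
#' Computes all n(n-1)/2 pairwise weights of a recording with the selected
#' estimator, vectorized over channels (the coherence measures share one
#' Welch cross-spectral decomposition; PLI shares one analytic-signal pass).
#' For `"PLI"` and `"CORR"` the band restriction is expected to come from an
#' upstream band-pass; `band` is recorded as metadata only.
#'
#' @param rec An [eeg_recording()] with at least 2 channels.
#' @param method One of `"MSC"`, `"iCOH"`, `"PLI"`, `"CORR"`.
#' @param band A [band_spec()] (required for MSC/iCOH).
#' @param sp [spectral_params()] for the coherence measures.
#' @param trim_frac PLI edge trim fraction.
#' @return An object of class `connectivity_matrix`: fields `weights`
#'   (symmetric, zero-diagonal, in \[0,1\]), `method`, `band`,
#'   `channel_labels`.
#' @export
connectivity_matrix <- function(rec, method, band = NULL,
                                sp = spectral_params(), trim_frac = 0.1) {
  if (!method %in% conn_methods)
    stop("unknown method '", method, "'; valid methods: ",
         paste(conn_methods, collapse = ", "))
  nch <- n_channels(rec)
  if (nch < 2) stop("need at least 2 channels")
  X <- rec$data
  W <- matrix(0, nch, nch)
  if (method %in% c("MSC", "iCOH")) {
    if (is.null(band)) stop(method, " requires a band")
    cs <- welch_csd(X, rec$fs, sp)
    bins <- band_bins(cs$freq, band)
    auto <- vapply(seq_len(nch), function(i) Re(cs$S[, i, i]), numeric(length(cs$freq)))
    for (i in seq_len(nch - 1)) for (j in (i + 1):nch) {
      K <- cs$S[bins, i, j] / sqrt(pmax(auto[bins, i] * auto[bins, j],
                                        .Machine$double.xmin))
      W[i, j] <- if (method == "MSC") mean(Mod(K)^2) else mean(abs(Im(K)))
    }
  } else if (method == "PLI") {
    idx <- pli_keep_idx(ncol(X), trim_frac)
    ph <- matrix(0, nch, length(idx))
    for (i in seq_len(nch)) ph[i, ] <- Arg(analytic_signal(X[i, ]))[idx]
    for (i in seq_len(nch - 1)) for (j in (i + 1):nch)
      W[i, j] <- abs(mean(sign(wrap_phase(ph[i, ] - ph[j, ]))))
  } else {                                       # CORR
    W[upper.tri(W)] <- abs(cor(t(X)))[upper.tri(W)]
  }
  W <- W + t(W)
  W <- pmin(pmax(W, 0), 1)
  diag(W) <- 0
  dimnames(W) <- list(rec$channel_labels, rec$channel_labels)
  structure(list(weights = W, method = method, band = band,
                 channel_labels = rec$channel_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", x$method,
      if (!is.null(x$band)) paste0(" [", x$band$name, "]"), ", ",
      length(x$channel_labels), " channels\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.connectivity_matrix <- function(x, ...) x$weights

#' Serialize a connectivity matrix
#'
#' `write_conn_matrix` writes the square labeled matrix as tab-separated
#' text; `conn_edge_list` returns the long-format edge list
#' (node_i, node_j, weight) over the upper triangle.
#'
#' @param mat A `connectivity_matrix`.
#' @param path Output path.
#' @return `path` invisibly, or a data.frame for `conn_edge_list`.
#' @export
write_conn_matrix <- function(mat, path) {
  write.table(mat$weights, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
conn_edge_list <- function(mat) {
  W <- mat$weights
  idx <- which(upper.tri(W), arr.ind = TRUE)
  data.frame(node_i = mat$channel_labels[idx[, 1]],
             node_j = mat$channel_labels[idx[, 2]],
             weight = W[idx], stringsAsFactors = FALSE)
}
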