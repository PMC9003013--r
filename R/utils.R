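# internal helpers shared across modules

# Deterministically derive a child seed from a base seed and an index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(base_seed, index) {
  v <- ((as.numeric(base_seed) %% 94906249) * 22695477 +
          as.numeric(index) * 104729) %% 2147483647
  as.integer(v)
}

# Symmetric Hann window (tapers to zero at both ends).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Analytic signal via the frequency-domain method: zero out negative
# frequencies, double positive ones, keep DC (and Nyquist for even n).
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(phi) {
  w <- phi %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
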