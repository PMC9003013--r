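full_band <- band_spec("Full", 0.5, 45)

test_that("MSC matches the naive per-segment DFT oracle", {
  for (s in c(11, 22, 33)) {
    withr::local_seed(s)
    x <- rnorm(500)
    y <- 0.6 * x + rnorm(500)
    expect_equal(msc(x, y, fs = 100, band = full_band),
                 oracle_msc(x, y, 100, 0.5, 45), tolerance = 1e-6)
    ks <- coherency_spectrum(x, y, fs = 100)
    oc <- oracle_coherency(x, y, 100)
    expect_lt(max(Mod(ks$coherency - oc$K)), 1e-6)
  }
})

test_that("connectivity identities hold to numerical precision", {
  t <- (0:999) / 100
  x <- sin(2 * pi * 10 * t)
  expect_equal(msc(x, x, 100, full_band), 1, tolerance = 1e-9)
  expect_lt(icoh(x, x, 100, full_band), 1e-9)
  expect_lt(icoh(x, 2 * x, 100, full_band), 1e-9)   # zero-lag mixing nulled
  expect_equal(pli(x, x), 0)
  expect_equal(pli(x, sin(2 * pi * 10 * t - pi / 2)), 1)  # constant lag locks
  expect_equal(pearson_abs(x, -3 * x), 1)
  expect_equal(pearson_abs(x, x + 5), 1)
})

test_that("a delayed scaled copy is near-perfectly coherent in band", {
  withr::local_seed(4)
  x <- rnorm(2000)
  y <- c(rep(0, 3), 0.5 * x[1:1997])
  # 2 s segments keep the window-misalignment loss of the 3-sample delay
  # negligible relative to the linear-filter coherence of 1
  expect_gt(msc(x, y, 100, band_spec("mid", 5, 40),
                sp = spectral_params(segment_len = 2)), 0.99)
})

test_that("a quadrature pair is purely imaginary-coherent in its band", {
  withr::local_seed(6)
  t <- (0:1999) / 100
  x <- sin(2 * pi * 9 * t) + 0.05 * rnorm(2000)
  y <- sin(2 * pi * 9 * t - pi / 2) + 0.05 * rnorm(2000)
  expect_gt(icoh(x, y, 100, band_spec("Alpha-1", 8, 10)), 0.9)
})

test_that("independent signals show low coupling", {
  withr::local_seed(9)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(msc(x, y, 100, full_band), 0.2)
  expect_lt(pearson_abs(x, y), 0.05)
})

test_that("PLI and |r| are invariant to positive amplitude scaling", {
  withr::local_seed(12)
  x <- rnorm(400); y <- rnorm(400)
  expect_equal(pli(2.5 * x, 0.3 * y), pli(x, y))
  expect_equal(pearson_abs(7 * x, 0.1 * y), pearson_abs(x, y))
})

test_that("all estimators stay in [0, 1] on random signal pairs", {
  withr::local_seed(13)
  for (i in 1:250) {
    x <- rnorm(300) * runif(1, 0.1, 10)
    y <- rnorm(300) * runif(1, 0.1, 10) + runif(1, -0.5, 0.5) * x
    vals <- c(msc(x, y, 100, full_band), icoh(x, y, 100, full_band),
              pli(x, y), pearson_abs(x, y))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("imaginary coherency never exceeds the coherency modulus", {
  withr::local_seed(14)
  x <- rnorm(1000); y <- 0.4 * x + rnorm(1000)
  K <- coherency_spectrum(x, y, 100)$coherency
  expect_true(all(abs(Im(K)) <= Mod(K) + 1e-12))
})

test_that("estimators reject malformed input", {
  expect_error(msc(rnorm(100), rnorm(99), 100, full_band), "length")
  expect_error(msc(rnorm(20), rnorm(20), 100, full_band), "too short")
  expect_error(pli(rnorm(50), rnorm(49)), "length")
  expect_error(pearson_abs(rep(1, 50), rnorm(50)), "zero-variance")
  expect_error(spectral_params(overlap_frac = 1), "overlap")
})

test_that("connectivity_matrix agrees with the pairwise estimators", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 4, duration = 6, seed = 2)
  rec <- bandpass_recording(generate_record(cfg, "PE", 17), full_band)
  for (method in c("MSC", "iCOH", "PLI", "CORR")) {
    cm <- connectivity_matrix(rec, method, band = full_band)
    W <- cm$weights
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
    expect_true(all(W >= 0 & W <= 1))
    pairwise <- function(i, j) switch(method,
      MSC = msc(rec$data[i, ], rec$data[j, ], rec$fs, full_band),
      iCOH = icoh(rec$data[i, ], rec$data[j, ], rec$fs, full_band),
      PLI = pli(rec$data[i, ], rec$data[j, ]),
      CORR = pearson_abs(rec$data[i, ], rec$data[j, ]))
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(W[i, j], pairwise(i, j), tolerance = 1e-10)
  }
  expect_error(connectivity_matrix(rec, "granger"), "valid methods")
})

test_that("a 19-channel record yields 171 pairwise weights, ~1 under full coupling", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 19, duration = 5,
                       coupling_pe = 1, noise_sd = 0, lag_max = 0, seed = 31)
  rec <- generate_record(cfg, "PE", 7)
  cm <- connectivity_matrix(rec, "CORR")
  expect_equal(sum(upper.tri(cm$weights)), 171)
  expect_true(all(cm$weights[upper.tri(cm$weights)] > 0.999))
  el <- conn_edge_list(cm)
  expect_equal(nrow(el), 171)
})
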