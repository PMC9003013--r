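test_that("EDF files round-trip within 16-bit quantization", {
  cfg <- cohort_config(n_per_group = 2, n_channels = 19, fs = 100,
                       duration = 2, seed = 5)
  rec <- generate_record(cfg, "PC", 9, subject_id = "P01")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)
  expect_equal(n_channels(back), 19)
  expect_equal(back$fs, 100)
  expect_identical(back$channel_labels, rec$channel_labels)
  qstep <- (max(rec$data) - min(rec$data)) / 65535
  expect_lt(max(abs(back$data - rec$data)), 2 * qstep)
})

test_that("delimited matrices round-trip and demand a sampling rate", {
  rec <- eeg_recording(matrix(rnorm(40), 4, 10), fs = 50,
                       channel_labels = c("Fp1", "Fp2", "O1", "O2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recording(rec, path)
  back <- read_recording(path)   # fs from the '# fs' declaration
  expect_equal(back$fs, 50)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_lt(max(abs(back$data - rec$data)), 1e-8)
  # strip the declaration: now fs_hint is mandatory
  writeLines(readLines(path)[-1], path)
  expect_error(read_recording(path), "fs_hint")
  expect_equal(read_recording(path, fs_hint = 50)$fs, 50)
})

test_that("resampling rescales length and preserves band-limited content", {
  t500 <- (0:4999) / 500
  rec <- eeg_recording(rbind(sin(2 * pi * 10 * t500), cos(2 * pi * 7 * t500)),
                       fs = 500, channel_labels = c("a", "b"))
  out <- resample_recording(rec, 100)
  expect_equal(n_samples(out), 1000)
  expect_equal(out$fs, 100)
  ref <- sin(2 * pi * 10 * (0:999) / 100)
  expect_gt(cor(out$data[1, ], ref), 0.999)
  expect_identical(out$channel_labels, rec$channel_labels)
  same <- resample_recording(rec, 500)
  expect_equal(same$data, rec$data)
  expect_error(resample_recording(out, 200), "up-sampling")
})

test_that("band-pass attenuates out-of-band sinusoids by at least 20 dB", {
  fs <- 100
  t <- (0:(20 * fs - 1)) / fs
  x <- sin(2 * pi * 2 * t) + sin(2 * pi * 20 * t)
  rec <- eeg_recording(matrix(x, 1), fs = fs)
  out <- bandpass_recording(rec, band_spec("Beta", 12, 30))$data[1, ]
  power_at <- function(sig, f) {
    n <- length(sig)
    Mod(sum(sig * exp(-2i * pi * f * (0:(n - 1)) / fs)))^2 / n
  }
  expect_lt(power_at(out, 2) / power_at(out, 20), 0.01)
})

test_that("white noise through Delta keeps >80% of variance below 5 Hz", {
  withr::local_seed(2)
  fs <- 100
  rec <- eeg_recording(matrix(rnorm(60 * fs), 1), fs = fs)
  out <- bandpass_recording(rec, band_spec("Delta", 0.5, 4))$data[1, ]
  P <- Mod(fft(out))^2
  n <- length(out)
  freq <- (0:(n - 1)) * fs / n
  half <- freq <= fs / 2
  expect_gt(sum(P[half & freq < 5]) / sum(P[half]), 0.8)
})

test_that("filtering is zero-phase for in-band content", {
  fs <- 100
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 20 * t)
  out <- bandpass_recording(eeg_recording(matrix(x, 1), fs),
                            band_spec("Beta", 12, 30))$data[1, ]
  core <- 201:800  # away from edge effects
  bin_phase <- function(sig) Arg(sum(sig * exp(-2i * pi * 20 * (core - 1) / fs)))
  expect_lt(abs(bin_phase(out[core]) - bin_phase(x[core])), 1e-3)
})

test_that("band-pass is idempotent in band power", {
  withr::local_seed(7)
  fs <- 100
  rec <- eeg_recording(matrix(rnorm(30 * fs), 1), fs = fs)
  beta <- band_spec("Beta", 12, 30)
  once <- bandpass_recording(rec, beta)
  twice <- bandpass_recording(once, beta)
  bp <- function(r) {
    P <- Mod(fft(r$data[1, ]))^2
    freq <- (0:(n_samples(r) - 1)) * fs / n_samples(r)
    sum(P[freq >= 15 & freq <= 27])
  }
  expect_lt(abs(10 * log10(bp(twice) / bp(once))), 1)
})

test_that("band validation rejects edges outside (0, fs/2)", {
  rec <- eeg_recording(matrix(rnorm(500), 1), fs = 100)
  expect_error(bandpass_recording(rec, band_spec("bad", 10, 60)), "fs/2")
  expect_error(band_spec("bad", 0, 10), "low")
})

test_that("the six standard bands match the canonical definition", {
  b <- standard_bands()
  expect_length(b, 6)
  expect_equal(names(b), c("Delta", "Theta", "Alpha-1", "Alpha-2", "Beta", "Full"))
  expect_equal(c(b$Beta$low, b$Beta$high), c(12, 30))
  expect_equal(c(b$Delta$low, b$Delta$high), c(0.5, 4))
  expect_equal(c(b$Full$low, b$Full$high), c(0.5, 45))
  expect_true(all(vapply(b, function(x) x$low < x$high, TRUE)))
})

test_that("segment splitting follows the floor rule and folds the remainder", {
  mk <- function(secs) eeg_recording(matrix(rnorm(2 * secs * 10), 2), fs = 10,
                                     subject_id = "S", group = "PC")
  segs <- split_segments(mk(250), min_len = 100)
  expect_length(segs, 2)
  expect_equal(duration(segs[[1]]), 100)
  expect_equal(duration(segs[[2]]), 150)   # remainder folded into the last
  expect_equal(vapply(segs, `[[`, "", "group"), c("PC", "PC"))
  segs3 <- split_segments(mk(250), min_len = 100, discard_remainder = TRUE)
  expect_equal(duration(segs3[[2]]), 100)
  expect_length(split_segments(mk(100), min_len = 100), 1)
  expect_warning(short <- split_segments(mk(90), min_len = 100), "shorter")
  expect_length(short, 1)
  expect_equal(duration(short[[1]]), 90)
})
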