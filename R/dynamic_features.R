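#' Sliding-window plan
#'
#' @param width Window width in seconds (default 3).
#' @param step Step between window starts in seconds (default 1, i.e. 2/3
#'   overlap at the default width).
#' @return An object of class `window_plan`.
#' @export
window_plan <- function(width = 3, step = 1) {
  if (!(step > 0 && step <= width)) stop("need 0 < step <= width")
  structure(list(width = width, step = step), class = "window_plan")
}

#' Cut a recording into sliding windows
#'
#' Windows start at 0, `step`, `2*step`, ... seconds; each is exactly
#' `width` seconds; a trailing partial window is dropped, giving
#' `floor((duration - width) / step) + 1` windows.
#'
#' @param rec An [eeg_recording()] at least `width` seconds long.
#' @param plan A [window_plan()].
#' @return List of [eeg_recording()] windows, each carrying a
#'   `window_start` attribute in seconds.
#' @export
sliding_windows <- function(rec, plan = window_plan()) {
  dur <- duration(rec)
  if (dur < plan$width)
    stop("record (", dur, " s) shorter than the window width (", plan$width, " s)")
  nw <- floor((dur - plan$width) / plan$step + 1e-9) + 1
  wlen <- round(plan$width * rec$fs)
  lapply(seq_len(nw) - 1, function(w) {
    from <- round(w * plan$step * rec$fs) + 1
    win <- eeg_recording(rec$data[, from:(from + wlen - 1), drop = FALSE],
                         fs = rec$fs, channel_labels = rec$channel_labels,
                         subject_id = rec$subject_id, group = rec$group,
                         segment = rec$segment)
    attr(win, "window_start") <- w * plan$step
    win
  })
}

#' Per-window connectivity matrices
#'
#' Computes one `connectivity_matrix` per sliding window; used both for
#' dynamic threshold selection (windows enter the group average) and for the
#' topological time series.
#'
#' @inheritParams connectivity_matrix
#' @param plan A [window_plan()].
#' @return List of `connectivity_matrix` objects with a `"times"` attribute
#'   of window start times.
#' @export
window_matrices <- function(rec, method, band = NULL, plan = window_plan(),
                            sp = spectral_params()) {
  wins <- sliding_windows(rec, plan)
  mats <- lapply(wins, connectivity_matrix, method = method, band = band, sp = sp)
  attr(mats, "times") <- vapply(wins, attr, numeric(1), "window_start")
  mats
}

#' Topological feature time series over sliding windows
#'
#' For each window: connectivity matrix, proportional threshold (one global
#' proportion selected at cohort level), then the five static features. The
#' per-window random-graph seed is derived from `seed` and the window index
#' so the series is reproducible.
#'
#' @inheritParams window_matrices
#' @param proportion Edge-removal proportion from [select_threshold()].
#' @param n_random Random graphs per window for the small-world index.
#' @param seed Base seed.
#' @param mats Optional precomputed result of [window_matrices()] (then
#'   `rec`/`method`/`band`/`plan`/`sp` are ignored).
#' @return A `topology_series`: `times`, `values` (windows x 5 matrix),
#'   `n_components` per window.
#' @export
topology_series <- function(rec, method, band = NULL, proportion = 0,
                            plan = window_plan(), sp = spectral_params(),
                            n_random = 20, seed = 1, mats = NULL) {
  if (is.null(mats)) mats <- window_matrices(rec, method, band, plan, sp)
  times <- attr(mats, "times") %||% seq_along(mats) - 1
  vals <- matrix(0, length(mats), 5,
                 dimnames = list(NULL, static_feature_names))
  ncomp <- integer(length(mats))
  for (w in seq_along(mats)) {
    g <- apply_threshold(mats[[w]], proportion)
    f <- static_features(g, n_random = n_random, seed = derive_seed(seed, w),
                         quiet = TRUE)
    vals[w, ] <- f
    ncomp[w] <- attr(f, "n_components")
  }
  structure(list(times = times, values = vals, n_components = ncomp),
            class = "topology_series")
}

#' @export
print.topology_series <- function(x, ...) {
  cat("<topology_series> ", nrow(x$values), " windows x ",
      ncol(x$values), " features\n", sep = "")
  invisible(x)
}

dynamic_stats <- c(mean = "mean", sd = "sd", median = "median", iqr = "iqr")

dynamic_feature_names <- function() {
  as.vector(vapply(static_feature_names,
                   function(f) paste(names(dynamic_stats), f, sep = "_"),
                   character(4)))
}

#' Summarize a topological time series into dynamic features
#'
#' Mean, standard deviation (sample, n-1), median and interquartile range
#' (linear-interpolation quantiles) of each of the five per-window features:
#' 20 values named `{stat}_{feature}` in fixed feature-major order.
#'
#' @param series A `topology_series` with at least 2 windows.
#' @return Named numeric vector of length 20.
#' @export
summarize_series <- function(series) {
  v <- series$values
  if (nrow(v) < 2) stop("need at least 2 windows (SD undefined otherwise)")
  out <- as.vector(apply(v, 2, function(col)
    c(mean(col), sd(col), median(col), IQR(col))))
  names(out) <- dynamic_feature_names()
  out
}

#' Export a topology series in long format
#'
#' @param series A `topology_series`.
#' @param sample_id Identifier column value.
#' @return data.frame with columns sample_id, window_start, feature, value.
#' @export
series_long <- function(series, sample_id = NA_character_) {
  data.frame(sample_id = sample_id,
             window_start = rep(series$times, ncol(series$values)),
             feature = rep(colnames(series$values), each = nrow(series$values)),
             value = as.vector(series$values), stringsAsFactors = FALSE)
}
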