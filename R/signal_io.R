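#' Multichannel EEG recording
#'
#' Container for a labeled multichannel signal: a channels x samples numeric
#' matrix (microvolts by convention), a sampling rate, ordered channel labels,
#' and optional subject/group metadata.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of channel names, one per row of
#'   `data`. Defaults to `Ch1..Chn`.
#' @param subject_id Optional subject identifier.
#' @param group Optional group label (e.g. `"PC"` or `"PE"`).
#' @param segment Optional segment index when the recording is a split
#'   fragment of a longer record.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2, 100), fs = 100)
#' n_channels(rec); duration(rec)
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, subject_id = NA_character_,
                          group = NA_character_, segment = NA_integer_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- rownames(data) %||% paste0("Ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length (", length(channel_labels),
         ") must equal the number of channels (", nrow(data), ")")
  if (any(!is.finite(data)))
    stop("recording contains non-finite values")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = as.numeric(fs),
                 channel_labels = as.character(channel_labels),
                 subject_id = subject_id, group = group, segment = segment),
            class = "eeg_recording")
}

#' @rdname eeg_recording
#' @param rec An `eeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname eeg_recording
#' @export
duration <- function(rec) ncol(rec$data) / rec$fs

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", n_channels(x), " channels x ", n_samples(x),
      " samples @ ", x$fs, " Hz (", round(duration(x), 2), " s)\n", sep = "")
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  if (!is.na(x$group)) cat("  group:  ", x$group, "\n")
  invisible(x)
}

#' Frequency band specification
#'
#' @param name Band name.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(name, low, high) {
  if (!(low > 0 && high > low))
    stop("band edges must satisfy 0 < low < high; got [", low, ", ", high, "]")
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat("<band_spec> ", x$name, ": ", x$low, "-", x$high, " Hz\n", sep = "")
  invisible(x)
}

#' The six standard EEG frequency bands
#'
#' Delta (0.5-4 Hz), Theta (4-8), Alpha-1 (8-10), Alpha-2 (10-12),
#' Beta (12-30), and the full band (0.5-45 Hz).
#'
#' @return Named list of six [band_spec()] objects.
#' @examples
#' names(standard_bands())
#' @export
standard_bands <- function() {
  bands <- list(
    band_spec("Delta",   0.5,  4),
    band_spec("Theta",   4,    8),
    band_spec("Alpha-1", 8,   10),
    band_spec("Alpha-2", 10,  12),
    band_spec("Beta",    12,  30),
    band_spec("Full",    0.5, 45)
  )
  names(bands) <- vapply(bands, `[[`, "", "name")
  bands
}

#' Read a recording from an EDF or delimited-text file
#'
#' EDF files (`.edf`) are read with the built-in 16-bit EDF reader. Any other
#' extension is treated as delimited text in the package's matrix layout: an
#' optional `# fs <Hz>` comment line, a header line of tab-separated channel
#' labels, then one line per channel. Delimited input requires a sampling rate
#' from either the `# fs` line or `fs_hint`.
#'
#' @param path File path.
#' @param fs_hint Sampling rate in Hz for delimited input lacking an
#'   `# fs` declaration. Ignored for EDF.
#' @return An [eeg_recording()].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, fs_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(read_edf(path))
  lines <- readLines(path)
  fs <- fs_hint
  if (length(lines) && grepl("^#\\s*fs\\b", lines[1])) {
    fs <- as.numeric(sub("^#\\s*fs[ =\t]+", "", lines[1]))
    lines <- lines[-1]
  }
  if (is.null(fs) || is.na(fs))
    stop("delimited input needs a sampling rate: add a '# fs <Hz>' line or pass fs_hint")
  if (length(lines) < 2) stop("delimited matrix needs a header line and at least one channel row")
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rows <- lapply(lines[-1], function(l) as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
  ns <- unique(lengths(rows))
  if (length(ns) != 1) stop("channel rows have unequal lengths")
  data <- do.call(rbind, rows)
  if (length(labels) != nrow(data))
    stop("header has ", length(labels), " labels but file has ", nrow(data), " channel rows")
  eeg_recording(data, fs = fs, channel_labels = labels)
}

#' Write a recording to an EDF or delimited-text file
#'
#' The format follows the file extension: `.edf` for 16-bit EDF, anything
#' else for the delimited matrix layout read by [read_recording()].
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) return(write_edf(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# fs", format(rec$fs, digits = 12)), con)
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  for (i in seq_len(n_channels(rec)))
    writeLines(paste(format(rec$data[i, ], digits = 10, trim = TRUE, scientific = TRUE),
                     collapse = "\t"), con)
  invisible(path)
}

#' Down-sample a recording
#'
#' Fourier-domain resampling: the spectrum is truncated at the new Nyquist
#' frequency and inverted, which is zero-phase and exact for band-limited
#' content. Only down-sampling is supported.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs New sampling rate in Hz, `<= rec$fs`.
#' @return The resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs)
    stop("up-sampling not supported: target_fs (", target_fs,
         ") exceeds the recording rate (", rec$fs, ")")
  if (target_fs == rec$fs) return(rec)
  n <- n_samples(rec)
  n_out <- round(n * target_fs / rec$fs)
  out <- t(apply(rec$data, 1, fft_resample, n_out = n_out))
  eeg_recording(out, fs = target_fs, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, group = rec$group, segment = rec$segment)
}

fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  keep <- floor(n_out / 2)
  Y <- complex(length.out = n_out)
  Y[1:(keep + 1)] <- X[1:(keep + 1)]
  if (keep > 0) Y[(n_out - keep + 1):n_out] <- X[(n - keep + 1):n]
  if (n_out %% 2 == 0) Y[keep + 1] <- Re(Y[keep + 1])  # real Nyquist bin
  Re(fft(Y, inverse = TRUE)) / n
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a linear-phase (symmetric) Hamming-window FIR
#' band-pass whose group delay is compensated exactly, so no phase shift is
#' introduced between channels -- a requirement for the phase-based
#' connectivity estimators. The transition bandwidth is 25% of the lower band
#' edge; the kernel length is capped at one third of the signal so short
#' records remain filterable. Edges are handled by odd reflection padding.
#'
#' @param rec An [eeg_recording()].
#' @param band A [band_spec()] (or element of [standard_bands()]).
#' @return The filtered [eeg_recording()].
#' @export
bandpass_recording <- function(rec, band) {
  fs <- rec$fs
  if (!(band$low > 0 && band$high < fs / 2))
    stop("band [", band$low, ", ", band$high, "] Hz outside (0, fs/2) = (0, ",
         fs / 2, ") Hz")
  h <- fir_bandpass(fs, band$low, band$high, n_samples(rec))
  out <- t(apply(rec$data, 1, fir_zerophase, h = h))
  eeg_recording(out, fs = fs, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, group = rec$group, segment = rec$segment)
}

# Hamming-window FIR band-pass taps; odd length (type-I linear phase).
fir_bandpass <- function(fs, low, high, n_sig) {
  trans <- 0.25 * low
  ntaps <- ceiling(3.3 * fs / trans)           # Hamming transition ~ 3.3/N
  cap <- max(33, floor(n_sig / 3))
  ntaps <- min(ntaps, cap)
  if (ntaps %% 2 == 0) ntaps <- ntaps - 1
  signal::fir1(ntaps - 1, c(low, high) / (fs / 2), type = "pass")
}

# Apply a symmetric FIR with exact group-delay compensation (zero phase).
# FFT convolution keeps long kernels cheap.
fir_zerophase <- function(x, h) {
  n <- length(x)
  d <- (length(h) - 1) / 2
  pad <- min(d, n - 1)
  left  <- 2 * x[1] - x[(pad + 1):2]            # odd reflection
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- signal::fftfilt(h, c(xp, numeric(d)))    # causal; delay = d
  y[(pad + d + 1):(pad + d + n)]
}

#' Split a recording into consecutive segments
#'
#' Cuts the record into `floor(duration / min_len)` non-overlapping segments
#' of at least `min_len` seconds. A trailing remainder shorter than `min_len`
#' is appended to the final segment (or discarded with
#' `discard_remainder = TRUE`). A record shorter than `min_len` is returned
#' whole with a warning.
#'
#' @param rec An [eeg_recording()].
#' @param min_len Minimum segment length in seconds.
#' @param discard_remainder Drop the trailing remainder instead of folding it
#'   into the last segment.
#' @return List of [eeg_recording()] segments inheriting `subject_id` and
#'   `group`, numbered via the `segment` field.
#' @export
split_segments <- function(rec, min_len = 100, discard_remainder = FALSE) {
  if (min_len <= 0) stop("min_len must be positive")
  dur <- duration(rec)
  k <- floor(dur / min_len + 1e-9)
  if (k < 1) {
    warning("record of ", round(dur, 2), " s is shorter than min_len = ",
            min_len, " s; returned whole")
    rec$segment <- 1L
    return(list(rec))
  }
  seg_samp <- floor(min_len * rec$fs)
  n <- n_samples(rec)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    from <- (i - 1) * seg_samp + 1
    to <- if (i == k && !discard_remainder) n else i * seg_samp
    out[[i]] <- eeg_recording(rec$data[, from:to, drop = FALSE], fs = rec$fs,
                              channel_labels = rec$channel_labels,
                              subject_id = rec$subject_id, group = rec$group,
                              segment = i)
  }
  out
}
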