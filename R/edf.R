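# Minimal 16-bit EDF (European Data Format) reader/writer.
#
# Layout: 256-byte fixed ASCII header, 256 bytes per signal of per-signal
# ASCII fields, then data records of little-endian int16 samples scaled
# linearly between the declared physical and digital ranges. One data record
# per second is written, so the sample count must be a whole number of
# seconds at an integer sampling rate.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a recording as 16-bit EDF
#'
#' Physical ranges are taken per channel from the data; quantization error is
#' bounded by (physical range)/65535.
#'
#' @param rec An [eeg_recording()] with integer `fs` and a whole number of
#'   seconds of data.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n <- n_samples(rec)
  if (n %% fs != 0) stop("EDF writer requires a whole number of seconds of data")
  nrec <- n / fs
  ns <- n_channels(rec)

  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id %||% "X", 80),
    edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(nrec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4)
  )
  writeBin(charToRaw(hdr), con)
  fields <- c(
    vapply(rec$channel_labels, edf_pad, "", width = 16),
    rep(edf_pad("", 80), ns),                 # transducer
    rep(edf_pad("uV", 8), ns),                # physical dimension
    vapply(pmin, edf_num, "", width = 8),
    vapply(pmax, edf_num, "", width = 8),
    rep(edf_pad(dmin, 8), ns),
    rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns),                 # prefiltering
    rep(edf_pad(fs, 8), ns),                  # samples per record
    rep(edf_pad("", 32), ns)
  )
  writeBin(charToRaw(paste(fields, collapse = "")), con)

  # re-read the header's printed physical ranges so scaling matches exactly
  pmin_h <- as.numeric(vapply(pmin, edf_num, "", width = 8))
  pmax_h <- as.numeric(vapply(pmax, edf_num, "", width = 8))
  pmin_h <- pmin(pmin_h, pmin); pmax_h <- pmax(pmax_h, pmax)

  dig <- matrix(0L, ns, n)
  for (i in seq_len(ns)) {
    v <- (rec$data[i, ] - pmin_h[i]) / (pmax_h[i] - pmin_h[i])
    dig[i, ] <- as.integer(round(v * (dmax - dmin) + dmin))
  }
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path Path to an EDF file.
#' @return An [eeg_recording()] (fs from the header; all signals must share
#'   one sampling rate).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) rawToChar(readBin(con, "raw", w))
  rd(8)                                   # version
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(trimws(rd(8)))
  recdur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  fld <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1)
    stop("EDF reader supports a single common sampling rate; got ",
         paste(unique(spr), collapse = ", "))
  fs <- spr[1] / recdur
  data <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = ns * spr[1], size = 2,
                     endian = "little", signed = TRUE)
    m <- matrix(block, nrow = spr[1], ncol = ns)
    data[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(m)
  }
  for (i in seq_len(ns))
    data[i, ] <- (data[i, ] - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax[i] - pmin[i]) + pmin[i]
  eeg_recording(data, fs = fs, channel_labels = labels,
                subject_id = if (nzchar(patient)) patient else NA_character_)
}
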