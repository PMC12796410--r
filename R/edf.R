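# Minimal EDF (European Data Format, 16-bit standard dialect) I/O.
# One data record per second; all channels share the sampling rate.
# Values are quantized to int16 over a per-channel symmetric physical range,
# so round-trips are exact to ~range/2^16.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

num_field <- function(x, width) {
  s <- formatC(signif(x, 7), format = "g", width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  pad_field(s, width)
}

#' Write / read a recording in EDF format
#'
#' Implements the 16-bit standard EDF dialect with one-second data records.
#' The recording length must be a whole number of seconds and the sampling
#' rate a whole number of samples per second.
#'
#' @param rec An `eeg_recording`.
#' @param path Path to the `.edf` file.
#' @return `write_recording_edf` returns `path` invisibly;
#'   `read_recording_edf` returns an `eeg_recording`.
#' @export
write_recording_edf <- function(rec, path) {
  rate <- rec$rate_hz
  if (rate != round(rate)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$data); nsamp <- ncol(rec$data)
  if (nsamp %% rate != 0) stop("EDF writer requires a whole number of seconds")
  n_rec <- nsamp %/% rate

  # per-channel symmetric physical range covering the data; integer bounds
  # print exactly in the 8-character header fields, so no clipping occurs
  pmax <- pmax(ceiling(apply(abs(rec$data), 1L, max)), 1)
  pmin <- -pmax
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field(sprintf("Startdate 01-JAN-2026 P%s %s", rec$participant_id,
                      rec$condition), 80),
    pad_field("01.01.26", 8),
    pad_field("00.00.00", 8),
    pad_field(as.character(256L * (1L + ns)), 8),
    pad_field("", 44),
    pad_field(as.character(n_rec), 8),
    pad_field("1", 8),
    pad_field(as.character(ns), 4))
  sig_hdr <- paste0(
    paste(vapply(rec$channel_labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(pmin, num_field, "", width = 8), collapse = ""),
    paste(vapply(pmax, num_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(as.character(dmin), 8), ns), collapse = ""),
    paste(rep(pad_field(as.character(dmax), 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(as.character(rate), 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  # re-read the headers' printed physical range so scaling is self-consistent
  pmin_r <- as.numeric(vapply(pmin, num_field, "", width = 8))
  pmax_r <- as.numeric(vapply(pmax, num_field, "", width = 8))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (s in seq_len(ns)) {
      d <- as.integer(round((rec$data[s, idx] - pmin_r[s]) * scale[s]) + dmin)
      d[d < dmin] <- dmin; d[d > dmax] <- dmax
      writeBin(d, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @param participant_id,condition Metadata to attach to the returned object
#'   (EDF's own annotation fields are not parsed).
#' @export
read_recording_edf <- function(path, participant_id = NA, condition = "pre") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes (implied by ns)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)          # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single shared sampling rate only")
  rate <- spr[1L] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                   endian = "little")
      out[s, idx] <- (d - dmin[s]) * (pmax[s] - pmin[s]) /
        (dmax[s] - dmin[s]) + pmin[s]
    }
  }
  recording(out, rate_hz = rate, channel_labels = labels,
            participant_id = participant_id, condition = condition)
}
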