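#' Multichannel EEG recording container
#'
#' Holds one participant x condition signal block as a channels x samples
#' numeric matrix together with its sampling rate and channel labels.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param rate_hz Sampling rate in samples/second.
#' @param channel_labels Character vector of channel names; defaults to
#'   rownames of `data` or generated labels.
#' @param participant_id Participant identifier (any scalar).
#' @param condition `"pre"` or `"post"`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, rate_hz, channel_labels = NULL,
                      participant_id = NA, condition = c("pre", "post")) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L) stop("a recording needs at least 2 channels")
  if (anyNA(data)) stop("recording contains NaN/NA samples")
  if (!(is.numeric(rate_hz) && length(rate_hz) == 1L && rate_hz > 0))
    stop("rate_hz must be a positive scalar")
  if (is.null(channel_labels)) {
    channel_labels <- rownames(data)
    if (is.null(channel_labels))
      channel_labels <- sprintf("E%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must match number of channels")
  rownames(data) <- channel_labels
  structure(list(participant_id = participant_id, condition = condition,
                 channel_labels = channel_labels, rate_hz = rate_hz,
                 data = data),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> participant %s, %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              as.character(x$participant_id), x$condition, nrow(x$data),
              ncol(x$data), x$rate_hz, ncol(x$data) / x$rate_hz))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$rate_hz

#' Standard 10-20 labels for a 19-channel montage
#'
#' For other channel counts generic `E01, E02, ...` labels are returned.
#'
#' @param n_channels Number of channels.
#' @return Character vector of labels.
#' @export
montage_labels <- function(n_channels) {
  if (n_channels == 19L)
    return(c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
             "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz", "Pz"))
  sprintf("E%02d", seq_len(n_channels))
}

#' Write / read a recording as a delimited text matrix
#'
#' Layout: one header row of channel labels, one column per channel, one row
#' per sample (the common ASCII EEG export layout). The sampling rate is not
#' stored in the file and must be supplied to the reader.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `write_recording_txt` returns `path` invisibly;
#'   `read_recording_txt` returns an `eeg_recording`.
#' @export
write_recording_txt <- function(rec, path, sep = ",") {
  m <- t(rec$data)                      # samples x channels
  utils::write.table(m, path, sep = sep, row.names = FALSE,
                     col.names = rec$channel_labels, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_txt
#' @param rate_hz Sampling rate of the stored signal.
#' @param participant_id,condition Metadata to attach.
#' @export
read_recording_txt <- function(path, rate_hz, participant_id = NA,
                               condition = "pre", sep = ",") {
  m <- as.matrix(utils::read.table(path, sep = sep, header = TRUE,
                                   check.names = FALSE))
  recording(t(m), rate_hz = rate_hz, channel_labels = colnames(m),
            participant_id = participant_id, condition = condition)
}
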