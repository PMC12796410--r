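# Band-pass filtering, epoching, and weighted Phase Lag Index estimation.

# linear convolution via FFT
conv_fft <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nf <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(a, rep(0, nf - length(a)))) *
                  stats::fft(c(b, rep(0, nf - length(b)))),
                inverse = TRUE))[seq_len(n)] / nf
}

# FIR order and taps for a band, Hamming-window design.
# Transition bandwidth per edge: min(max(0.25*edge, 2 Hz), edge); the filter
# order follows the usual Hamming heuristic 3.3 / (tb / rate).
fir_band_taps <- function(band, rate_hz, n_samples) {
  tb_low <- min(max(0.25 * band$low_hz, 2), band$low_hz)
  tb_high <- min(max(0.25 * band$high_hz, 2), band$high_hz)
  tb <- min(tb_low, tb_high)
  ord <- ceiling(3.3 / (tb / rate_hz))
  ord <- ord + ord %% 2L                     # even order, odd-length taps
  ord <- min(ord, max(2L, 2L * ((n_samples - 1L) %/% 2L)))
  signal::fir1(ord, c(band$low_hz, band$high_hz) * 2 / rate_hz, type = "pass")
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a linear-phase FIR band-pass (Hamming-window design, transition
#' bandwidth 25% of each band edge with a 2 Hz floor) forward and backward,
#' so the effective magnitude response is the squared FIR response and the
#' phase response is exactly zero. Implemented as a single FFT convolution
#' with the forward-backward kernel; edge regions of roughly one filter
#' length carry the usual zero-padding transient.
#'
#' @param rec An `eeg_recording`.
#' @param band A [band_spec()]; must lie below Nyquist.
#' @return A filtered `eeg_recording` of the same shape.
#' @export
bandpass <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_spec"))
  check_band_nyquist(band, rec$rate_hz)
  h <- fir_band_taps(band, rec$rate_hz, ncol(rec$data))
  g <- conv_fft(h, rev(h))                   # zero-phase kernel, |H|^2
  L <- length(h)
  n <- ncol(rec$data)
  nf <- stats::nextn(n + length(g) - 1L, 2)
  gf <- stats::fft(c(g, rep(0, nf - length(g))))
  pad <- matrix(0, nf, nrow(rec$data))
  pad[seq_len(n), ] <- t(rec$data)
  y <- Re(stats::mvfft(stats::mvfft(pad) * gf, inverse = TRUE)) / nf
  out <- rec
  out$data[] <- t(y[L - 1L + seq_len(n), , drop = FALSE])
  out
}

#' Segment a recording into non-overlapping fixed-length epochs
#'
#' The trailing remainder shorter than one epoch is discarded.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length_s Epoch length in seconds (default 4).
#' @return An `epoch_set`: list of channels x L blocks plus geometry.
#' @export
epoch_recording <- function(rec, epoch_length_s = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- epoch_length_s * rec$rate_hz
  if (abs(L - round(L)) > 1e-9)
    stop("epoch_length_s * rate_hz must be an integer number of samples")
  L <- as.integer(round(L))
  n_ep <- ncol(rec$data) %/% L
  if (n_ep < 1L)
    stop(sprintf("recording (%.2f s) shorter than one %g-s epoch",
                 recording_duration(rec), epoch_length_s))
  epochs <- lapply(seq_len(n_ep), function(k)
    rec$data[, ((k - 1L) * L + 1L):(k * L), drop = FALSE])
  structure(list(epochs = epochs, epoch_length_s = epoch_length_s,
                 rate_hz = rec$rate_hz, channel_labels = rec$channel_labels,
                 participant_id = rec$participant_id,
                 condition = rec$condition),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (%d samples) x %d channels @ %g Hz\n",
              length(x$epochs), x$epoch_length_s,
              ncol(x$epochs[[1L]]), nrow(x$epochs[[1L]]), x$rate_hz))
  invisible(x)
}

#' Weighted Phase Lag Index connectivity matrix
#'
#' For each channel pair (i, j),
#' \deqn{wPLI_{ij} = \frac{|\sum_k \mathrm{Im}\, S_{ij,k}|}{\sum_k |\mathrm{Im}\, S_{ij,k}|}}
#' where k runs over all (epoch x in-band frequency bin) cross-spectral
#' samples from Hann-tapered per-epoch DFTs. This is the standard (not
#' debiased) wPLI, pooled over epochs and in-band bins in one ratio. Pairs
#' with zero denominator — including all pairs involving a zero-variance
#' channel — get wPLI = 0.
#'
#' @param epochs An `epoch_set` with at least 2 epochs.
#' @param band A [band_spec()]; bins with `low_hz <= f <= high_hz` (DC
#'   excluded) enter the pooled ratio.
#' @return A symmetric n x n matrix in \[0, 1\] with zero diagonal, classed
#'   `connectivity_matrix`, carrying `band`, `participant_id` and
#'   `condition` attributes.
#' @export
wpli <- function(epochs, band) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(band, "band_spec"))
  check_band_nyquist(band, epochs$rate_hz)
  if (length(epochs$epochs) < 2L)
    stop("wPLI needs at least 2 epochs (multiple cross-spectral samples)")
  nch <- nrow(epochs$epochs[[1L]])
  L <- ncol(epochs$epochs[[1L]])
  zero_var <- which(vapply(seq_len(nch), function(ch)
    all(vapply(epochs$epochs, function(e) stats::var(e[ch, ]) == 0, TRUE)),
    TRUE))
  if (length(zero_var) > 0L)
    warning(sprintf("zero-variance channel(s) %s: connectivity set to 0",
                    paste(epochs$channel_labels[zero_var], collapse = ", ")))
  bins <- pos_bins_in_band(L, epochs$rate_hz, band$low_hz, band$high_hz)
  if (length(bins) == 0L)
    stop(sprintf("no DFT bins fall inside band %s at resolution %.3f Hz",
                 band$name, epochs$rate_hz / L))
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))   # Hann

  num <- matrix(0, nch, nch)
  den <- matrix(0, nch, nch)
  for (e in epochs$epochs) {
    X <- stats::mvfft(t(e) * taper)[bins, , drop = FALSE]   # bins x channels
    for (b in seq_len(nrow(X))) {
      # Im(S_ij) = Im(v_i) Re(v_j) - Re(v_i) Im(v_j), formed from real outer
      # products so that the diagonal is exactly 0 and antisymmetry is exact
      re <- Re(X[b, ]); iv <- Im(X[b, ])
      im <- outer(iv, re) - outer(re, iv)
      num <- num + im
      den <- den + abs(im)
    }
  }
  w <- abs(num) / den
  w[den == 0] <- 0
  diag(w) <- 0
  # guarantee exact symmetry and bounds against last-ulp rounding artifacts
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w <- pmin(pmax(w, 0), 1)
  dimnames(w) <- list(epochs$channel_labels, epochs$channel_labels)
  structure(w, class = c("connectivity_matrix", "matrix"),
            band = band, participant_id = epochs$participant_id,
            condition = epochs$condition)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  b <- attr(x, "band")
  cat(sprintf("<connectivity_matrix> %d x %d wPLI, band %s (%.1f-%.1f Hz), participant %s/%s\n",
              nrow(x), ncol(x), b$name, b$low_hz, b$high_hz,
              as.character(attr(x, "participant_id")), attr(x, "condition")))
  cat(sprintf("  mean off-diagonal wPLI: %.3f\n",
              mean(x[upper.tri(x)])))
  invisible(x)
}

#' Band-filter, epoch and estimate wPLI in one call
#'
#' @param rec An `eeg_recording`.
#' @param band A [band_spec()].
#' @param epoch_length_s Epoch length in seconds.
#' @return A `connectivity_matrix`.
#' @export
connectivity <- function(rec, band, epoch_length_s = 4) {
  wpli(epoch_recording(bandpass(rec, band), epoch_length_s), band)
}

#' Write / read a connectivity matrix as square CSV
#'
#' The header row and first column hold channel labels.
#'
#' @param w A `connectivity_matrix` (or plain symmetric matrix).
#' @param path CSV path.
#' @return `write_connectivity_csv` returns `path` invisibly;
#'   `read_connectivity_csv` returns a numeric matrix with dimnames.
#' @export
write_connectivity_csv <- function(w, path) {
  utils::write.csv(as.data.frame(unclass(w)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(d)
}
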