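#' Frequency band specification
#'
#' A band is a half-open interval of frequencies used both for band-pass
#' filtering and for selecting cross-spectral bins when estimating wPLI.
#'
#' @param name Band name, e.g. `"delta"`, `"beta"`, or any custom label.
#' @param low_hz,high_hz Band edges in Hz; must satisfy `0 < low < high`.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("delta", 0.5, 4)
#' @export
band_spec <- function(name, low_hz, high_hz) {
  stopifnot(is.character(name), length(name) == 1L)
  low_hz <- as.numeric(low_hz); high_hz <- as.numeric(high_hz)
  if (!(is.finite(low_hz) && is.finite(high_hz) && low_hz > 0 && high_hz > low_hz))
    stop("band edges must satisfy 0 < low_hz < high_hz")
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %.2f-%.2f Hz\n", x$name, x$low_hz, x$high_hz))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' Delta is 0.5-4 Hz by default (the commonly used lower edge for a "< 4 Hz"
#' definition; some figures use 0.5-3.5 Hz, which can be obtained with
#' [band_spec()]).
#'
#' @return Named list of [band_spec()] objects: delta, theta, alpha, beta.
#' @export
default_bands <- function() {
  list(delta = band_spec("delta", 0.5, 4),
       theta = band_spec("theta", 4, 8),
       alpha = band_spec("alpha", 8, 13),
       beta  = band_spec("beta", 13, 30))
}

# validate a band against a sampling rate (Nyquist)
check_band_nyquist <- function(band, rate_hz) {
  if (band$high_hz >= rate_hz / 2)
    stop(sprintf("band '%s' upper edge %.2f Hz is at or above Nyquist (%.2f Hz)",
                 band$name, band$high_hz, rate_hz / 2))
  invisible(TRUE)
}
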