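delta <- default_bands()$delta
beta <- default_bands()$beta

sine_recording <- function(freq, duration = 60, rate = 256, nch = 2) {
  tt <- seq_len(duration * rate) / rate
  recording(t(sapply(seq_len(nch), function(i)
    sin(2 * pi * freq * tt + (i - 1) * pi / 3))), rate)
}

mid_section <- function(x) {
  n <- length(x)
  x[floor(n / 3):floor(2 * n / 3)]
}

test_that("band-pass passes in-band tones and rejects out-of-band tones", {
  rec <- sine_recording(2)
  f <- bandpass(rec, delta)
  gain <- sd(mid_section(f$data[1, ])) / sd(mid_section(rec$data[1, ]))
  expect_lt(abs(gain - 1), 0.05)            # amplitude preserved within 5%

  rec20 <- sine_recording(20)
  f20 <- bandpass(rec20, delta)
  att <- 20 * log10(sd(mid_section(f20$data[1, ])) /
                      sd(mid_section(rec20$data[1, ])))
  expect_lt(att, -20)                       # >= 20 dB down in the stopband
})

test_that("white noise filtered to beta keeps < 5% spectral mass out of band", {
  set.seed(4)
  rec <- recording(matrix(rnorm(2 * 60 * 256), 2), 256)
  f <- bandpass(rec, beta)
  x <- mid_section(f$data[1, ])
  pg <- Mod(fft(x))^2
  freqs <- (seq_along(pg) - 1) * 256 / length(pg)
  half <- freqs <= 128
  inband <- half & freqs >= 13 & freqs <= 30
  expect_lt(sum(pg[half & !inband]) / sum(pg[half]), 0.05)
})

test_that("band outside Nyquist is rejected", {
  rec <- sine_recording(2, duration = 10)
  expect_error(bandpass(rec, band_spec("hf", 100, 140)), "Nyquist")
})

test_that("epoching follows the floor rule and errors on short input", {
  rec <- sine_recording(2, duration = 120)
  ep <- epoch_recording(rec, 4)
  expect_length(ep$epochs, 30)              # 120 s -> 30 x 4 s
  expect_equal(ncol(ep$epochs[[1]]), 1024)  # 4 s at 256 Hz

  rec10 <- sine_recording(2, duration = 10)
  ep10 <- epoch_recording(rec10, 4)
  expect_length(ep10$epochs, 2)             # 2 s remainder discarded

  rec_short <- recording(matrix(rnorm(2 * 998), 2), 256)  # 3.9 s
  expect_error(epoch_recording(rec_short, 4), "shorter")
})

test_that("zero lag gives wPLI 0 and a quarter-cycle lag gives wPLI 1", {
  set.seed(21)
  # narrowband noise around 10 Hz; y = exact quarter-cycle delayed copy
  n <- 40 * 256
  k <- 2:(n / 2)
  f <- (k - 1) * 256 / n
  cc <- ifelse(f >= 9 & f <= 11, complex(real = rnorm(length(k)),
                                         imaginary = rnorm(length(k))), 0)
  spec <- rep(0 + 0i, n); spec[k] <- cc; spec[n - k + 2] <- Conj(cc)
  x <- Re(fft(spec, inverse = TRUE))
  d <- round(256 / (4 * 10))                # quarter period at 10 Hz
  y <- c(x[(d + 1):n], x[1:d])
  band10 <- band_spec("narrow", 8, 12)
  ep0 <- epoch_recording(recording(rbind(x, x), 256), 4)
  expect_equal(unclass(wpli(ep0, band10))[1, 2], 0)
  epq <- epoch_recording(recording(rbind(x, y), 256), 4)
  expect_equal(unclass(wpli(epq, band10))[1, 2], 1)
})

test_that("wPLI equals an independent naive-DFT oracle to 1e-10", {
  set.seed(31)
  rate <- 32; L <- 64
  epochs <- lapply(1:12, function(i) matrix(rnorm(4 * L), 4))
  ep <- epoch_recording(recording(do.call(cbind, epochs), rate), L / rate)
  w <- unclass(wpli(ep, band_spec("b", 3, 10)))
  w_o <- oracle_wpli(epochs, rate, 3, 10)
  expect_lt(max(abs(w - w_o)), 1e-10)
})

test_that("wPLI output is bounded, symmetric, zero-diagonal", {
  rec <- fixture_recording(seed = 13, duration_s = 40)
  w <- connectivity(rec, delta)
  expect_true(all(w >= 0 & w <= 1))
  expect_identical(unclass(w), t(unclass(w)))
  expect_true(all(diag(w) == 0))
  expect_error(wpli(epoch_recording(rec, 40), delta), "2 epochs")
})

test_that("permuting channels permutes the wPLI matrix consistently", {
  rec <- fixture_recording(seed = 17, duration_s = 24)
  perm <- c(3, 1, 6, 2, 5, 4)
  rec_p <- recording(rec$data[perm, ], rec$rate_hz,
                     channel_labels = rec$channel_labels[perm])
  w <- unclass(connectivity(rec, delta))
  w_p <- unclass(connectivity(rec_p, delta))
  expect_equal(w_p, w[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a zero-variance channel is retained, zeroed and warned about", {
  rec <- fixture_recording(seed = 19, duration_s = 24)
  rec$data[2, ] <- 0
  ep <- epoch_recording(rec, 4)
  expect_warning(w <- wpli(ep, delta), "zero-variance")
  expect_true(all(w[2, ] == 0) && all(w[, 2] == 0))
  expect_equal(dim(w), c(6L, 6L))
})

test_that("wPLI is insensitive to a common zero-lag source", {
  # high-SNR regime so estimator noise does not mask the formula property:
  # fully coupled communities plus empty between-community pairs, long
  # recording, wide band (many pooled cross-spectral samples)
  set.seed(53)
  g <- make_coupling_graph(subgroup_spec("segregated", 2, 1, 0, 3), beta, 6)
  for (s in 1:2) {
    r0 <- synthesize_recording(list(g), 240, 256,
                               noise = list(pink_gain = 1,
                                            zero_lag_mix_gain = 0), seed = s)
    r2 <- synthesize_recording(list(g), 240, 256,
                               noise = list(pink_gain = 1,
                                            zero_lag_mix_gain = 2), seed = s)
    shift <- max(abs(unclass(connectivity(r0, beta)) -
                       unclass(connectivity(r2, beta))))
    expect_lt(shift, 0.05)
  }
})

test_that("zero-lag-only coupling yields near-zero wPLI despite strong mixing", {
  set.seed(99)
  g <- make_coupling_graph(subgroup_spec("integrated", 1, 0.3, 0.3, 0),
                           beta, 6)
  rec <- synthesize_recording(list(g), 120, 256,
                              noise = list(pink_gain = 1,
                                           zero_lag_mix_gain = 4), seed = 2)
  w <- unclass(connectivity(rec, beta))
  expect_lt(mean(w[upper.tri(w)]), 0.1)
})

test_that("with no coupling, planted-edge pairs look like non-edge pairs", {
  set.seed(37)
  spec <- subgroup_spec("segregated", 2, 0.9, 0.1, 0)   # gain 0
  g <- make_coupling_graph(spec, delta, 16)
  rec <- synthesize_recording(list(g), 60, 256,
                              noise = list(pink_gain = 1, zero_lag_mix_gain = 0))
  w <- unclass(connectivity(rec, delta))
  planted <- w[g$edges]
  mask <- upper.tri(w); mask[g$edges] <- FALSE
  null_vals <- w[mask]
  p <- wilcox.test(planted, null_vals)$p.value
  expect_gt(p, 0.01)
})

test_that("planted edges carry materially higher wPLI than non-edges", {
  set.seed(41)
  spec <- subgroup_spec("segregated", 2, 0.9, 0.1, 2)
  g <- make_coupling_graph(spec, delta, 16)
  rec <- synthesize_recording(list(g), 120, 256,
                              noise = list(pink_gain = 1, zero_lag_mix_gain = 0))
  w <- unclass(connectivity(rec, delta))
  mask <- upper.tri(w); mask[g$edges] <- FALSE
  expect_gte(mean(w[g$edges]) - mean(w[mask]), 0.15)
})

test_that("connectivity matrices round-trip through square CSV", {
  rec <- fixture_recording(seed = 43, duration_s = 16)
  w <- connectivity(rec, delta)
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity_csv(w, path)
  w2 <- read_connectivity_csv(path)
  expect_equal(unclass(w), w2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("EDF files round-trip within 16-bit quantization error", {
  rec <- fixture_recording(seed = 47, duration_s = 8)
  path <- withr::local_tempfile(fileext = ".edf")
  write_recording_edf(rec, path)
  rec2 <- read_recording_edf(path, participant_id = "P01", condition = "pre")
  expect_equal(rec2$rate_hz, 256)
  expect_identical(rec2$channel_labels, rec$channel_labels)
  scale <- max(abs(rec$data))
  expect_lt(max(abs(rec2$data - rec$data)), scale / 32000)
})
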