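# Synthetic EEG-like cohort generator.
#
# Each recording is a sum, per frequency band, of band-limited Gaussian
# sources shared between coupled channels with a fixed nonzero phase offset
# (planted true coupling), plus per-channel 1/f ("pink") background noise and
# a zero-lag common source emulating volume conduction.  Band-limited sources
# are synthesized in the frequency domain (white Gaussian coefficients on the
# in-band bins, zero elsewhere), i.e. ideally filtered white noise, which
# gives realistic phase jitter across epochs; the phase offset is applied as
# a constant spectral rotation so every in-band frequency carries the same
# lag.

#' Latent subgroup template for planted network topology
#'
#' Two labels are supported. `"segregated"` draws a stochastic block model:
#' channels are split into `community_count` equal communities, pairs within
#' a community connect with `p_within` and across communities with
#' `p_between`. `"integrated"` draws density-matched uniform random edges
#' (`p_within == p_between` required), so the two templates differ in
#' topology, not in expected edge density.
#'
#' @param label `"segregated"` or `"integrated"`.
#' @param community_count Number of communities (ignored for integrated).
#' @param p_within,p_between Edge probabilities.
#' @param coupling_gain Amplitude of planted sources relative to unit pink
#'   noise.
#' @return A `subgroup_spec` object.
#' @export
subgroup_spec <- function(label = c("segregated", "integrated"),
                          community_count = 4L, p_within, p_between,
                          coupling_gain = 1) {
  label <- match.arg(label)
  stopifnot(p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            coupling_gain >= 0, community_count >= 1L)
  if (label == "segregated" && p_within < p_between)
    stop("segregated spec requires p_within >= p_between")
  if (label == "integrated" && abs(p_within - p_between) > 1e-12)
    stop("integrated spec requires p_within == p_between (uniform edges)")
  structure(list(label = label, community_count = as.integer(community_count),
                 p_within = p_within, p_between = p_between,
                 coupling_gain = coupling_gain),
            class = "subgroup_spec")
}

community_sizes <- function(n_channels, community_count) {
  base <- n_channels %/% community_count
  sizes <- rep(base, community_count)
  extra <- n_channels - base * community_count
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Expected edge density of a subgroup template
#' @param spec A [subgroup_spec()].
#' @param n_channels Number of channels.
#' @return Expected fraction of channel pairs carrying a planted edge.
#' @export
expected_density <- function(spec, n_channels) {
  tot <- choose(n_channels, 2)
  if (spec$label == "integrated") return(spec$p_within)
  sizes <- community_sizes(n_channels, spec$community_count)
  w <- sum(choose(sizes, 2))
  (spec$p_within * w + spec$p_between * (tot - w)) / tot
}

#' Draw a planted coupling graph from a subgroup template
#'
#' Every drawn edge carries a phase lag sampled uniformly from
#' \eqn{[\pi/8, 3\pi/8]} radians — strictly nonzero, so wPLI can see it.
#'
#' @param spec A [subgroup_spec()].
#' @param band A [band_spec()] the graph applies to.
#' @param n_channels Number of channels (>= 4).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param match_density Optional reference density; if the template's
#'   expected density differs from it by more than 10% an error is raised
#'   (guards the density-matched contrast between subgroup templates).
#' @return A `coupling_graph`: list with `n_channels`, `edges` (2-column
#'   matrix, `i < j`), `lags`, `band`, `gain`, `membership`, `label`.
#' @export
make_coupling_graph <- function(spec, band, n_channels, seed = NULL,
                                match_density = NULL) {
  stopifnot(inherits(spec, "subgroup_spec"), inherits(band, "band_spec"))
  if (n_channels < 4L) stop("need n_channels >= 4")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(match_density)) {
    ed <- expected_density(spec, n_channels)
    if (abs(ed - match_density) / match_density > 0.10)
      stop(sprintf(
        "expected density %.3f of '%s' template differs from reference %.3f by > 10%%",
        ed, spec$label, match_density))
  }
  if (spec$label == "segregated") {
    sizes <- community_sizes(n_channels, spec$community_count)
    membership <- rep(seq_along(sizes), sizes)
  } else {
    membership <- rep(1L, n_channels)
  }
  pairs <- which(upper.tri(diag(n_channels)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  p <- if (spec$label == "segregated")
    ifelse(membership[pairs[, 1L]] == membership[pairs[, 2L]],
           spec$p_within, spec$p_between)
  else rep(spec$p_within, nrow(pairs))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  colnames(edges) <- c("i", "j")
  lags <- stats::runif(nrow(edges), pi / 8, 3 * pi / 8)
  structure(list(n_channels = as.integer(n_channels), edges = edges,
                 lags = lags, band = band, gain = spec$coupling_gain,
                 membership = membership, label = spec$label),
            class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf("<coupling_graph> %s, band %s: %d channels, %d edges (density %.3f)\n",
              x$label, x$band$name, x$n_channels, nrow(x$edges),
              nrow(x$edges) / choose(x$n_channels, 2)))
  invisible(x)
}

# positive-frequency fft bin indices whose frequency lies in [low, high]
pos_bins_in_band <- function(n, rate_hz, low_hz, high_hz) {
  k <- 2:floor(n / 2)                    # skip DC; skip Nyquist bin
  f <- (k - 1) * rate_hz / n
  k[f >= low_hz & f <= high_hz]
}

#' Synthesize one multichannel recording from planted coupling graphs
#'
#' @param graphs List of `coupling_graph` objects, one per band; bands must
#'   not exceed Nyquist.
#' @param duration_s Duration in seconds (>= 4, one default epoch).
#' @param rate_hz Sampling rate.
#' @param noise List with `pink_gain` (per-channel 1/f background, unit
#'   total power times the gain) and `zero_lag_mix_gain` (common broadband
#'   source added identically to every channel — a volume-conduction
#'   confound that wPLI should suppress).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param participant_id,condition Metadata for the returned recording.
#' @return An `eeg_recording`, channels x (duration*rate) samples.
#' @export
synthesize_recording <- function(graphs, duration_s, rate_hz,
                                 noise = list(pink_gain = 1,
                                              zero_lag_mix_gain = 0.25),
                                 seed = NULL, participant_id = NA,
                                 condition = "pre") {
  if (inherits(graphs, "coupling_graph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1L)
  nch <- graphs[[1L]]$n_channels
  for (g in graphs) {
    stopifnot(inherits(g, "coupling_graph"), g$n_channels == nch)
    check_band_nyquist(g$band, rate_hz)
  }
  if (duration_s < 4) stop("duration must cover at least one 4-s epoch")
  n <- duration_s * rate_hz
  if (abs(n - round(n)) > 1e-9) stop("duration_s * rate_hz must be integer")
  n <- as.integer(round(n))
  if (!is.null(seed)) set.seed(seed)

  spec_mat <- matrix(0 + 0i, n, nch)     # frequency-domain accumulation
  cplx <- function(m) (stats::rnorm(m) + 1i * stats::rnorm(m)) / sqrt(2)

  for (g in graphs) {
    bins <- pos_bins_in_band(n, rate_hz, g$band$low_hz, g$band$high_hz)
    if (length(bins) == 0L || nrow(g$edges) == 0L || g$gain == 0) next
    amp <- g$gain / sqrt(length(bins))   # unit source power times gain
    for (e in seq_len(nrow(g$edges))) {
      cc <- cplx(length(bins)) * amp
      i <- g$edges[e, 1L]; j <- g$edges[e, 2L]
      spec_mat[bins, i] <- spec_mat[bins, i] + cc
      spec_mat[bins, j] <- spec_mat[bins, j] + cc * exp(-1i * g$lags[e])
    }
  }

  pg <- if (is.null(noise$pink_gain)) 1 else noise$pink_gain
  zg <- if (is.null(noise$zero_lag_mix_gain)) 0 else noise$zero_lag_mix_gain
  kpos <- 2:floor(n / 2)
  fpos <- (kpos - 1) * rate_hz / n
  pink_amp <- fpos^(-0.5)
  pink_amp <- pink_amp / sqrt(sum(pink_amp^2))   # unit total power
  if (pg > 0)
    for (ch in seq_len(nch))
      spec_mat[kpos, ch] <- spec_mat[kpos, ch] + pg * pink_amp * cplx(length(kpos))
  if (zg > 0) {
    zbins <- pos_bins_in_band(n, rate_hz, 0.5, min(45, rate_hz / 2 - 1e-9))
    zamp <- ((zbins - 1) * rate_hz / n)^(-0.5)
    zamp <- zamp / sqrt(sum(zamp^2))
    zc <- zg * zamp * cplx(length(zbins))
    spec_mat[zbins, ] <- spec_mat[zbins, ] + zc   # identical on all channels
  }

  # hermitian completion and inverse FFT; overall scale ~10 uV rms per unit gain
  full <- matrix(0 + 0i, n, nch)
  full[kpos, ] <- spec_mat[kpos, ]
  full[n - kpos + 2L, ] <- Conj(spec_mat[kpos, ])
  x <- Re(stats::mvfft(full, inverse = TRUE)) / n
  x <- t(x) * (10 * n / sqrt(2))
  recording(x, rate_hz = rate_hz, channel_labels = montage_labels(nch),
            participant_id = participant_id, condition = condition)
}

#' Behavioral effect configuration for the synthetic cohort
#'
#' All planted behavioral effects live here. Defaults emulate a cohort of
#' 5-7-year-olds with a working-memory advantage in subgroup 2 (the
#' segregated-network subgroup) on the second and third trials and a higher
#' proportion of girls in subgroup 2; device-use variables are independent
#' of subgroup by construction.
#'
#' @param wm2_shift,wm3_shift Additive mean shifts (score points) applied to
#'   subgroup 2 on working-memory trials 2 and 3.
#' @param girl_prob Length-2 probability of `girl` per subgroup.
#' @param wm_time3_shift Additive shift (minutes) on trial-3 completion time
#'   in subgroup 2.
#' @return A list of effect parameters.
#' @export
effect_config <- function(wm2_shift = 5.8, wm3_shift = 3.6,
                          girl_prob = c(0.20, 0.64), wm_time3_shift = 0.5) {
  stopifnot(length(girl_prob) == 2L, all(girl_prob >= 0 & girl_prob <= 1))
  list(wm2_shift = wm2_shift, wm3_shift = wm3_shift,
       girl_prob = girl_prob, wm_time3_shift = wm_time3_shift)
}

#' @rdname effect_config
#' @export
zero_effect_config <- function() {
  effect_config(wm2_shift = 0, wm3_shift = 0,
                girl_prob = c(11 / 31, 11 / 31), wm_time3_shift = 0)
}

# truncated normal by rejection (vectorized); counts are rounded >= 0
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

r_ordinal <- function(n, probs) {
  sample.int(length(probs), n, replace = TRUE, prob = probs) - 1L
}

#' Generate the behavioral / questionnaire table for a cohort
#'
#' Working-memory scores are truncated-normal counts; device-use variables
#' are ordinal draws (0 = < 1 h/day ... 3 = > 5 h/day) with distributions
#' independent of subgroup; sex composition and WM2/WM3 means depend on the
#' subgroup label through `cfg`.
#'
#' @param labels Integer vector of ground-truth subgroup labels (1 or 2).
#' @param cfg An [effect_config()].
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A `data.frame`, one row per participant.
#' @export
generate_behavioral <- function(labels, cfg = effect_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  g2 <- labels == 2L
  sex <- ifelse(stats::runif(n) < cfg$girl_prob[labels], "girl", "boy")
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    sex = sex,
    age_years = round(rtnorm(n, 6.1, 1.1, 4.5, 7.9), 1),
    errors = round(rtnorm(n, 3.7, 2.9, 0, Inf)),
    wm1 = round(rtnorm(n, 16.9, 7.7, 0, Inf)),
    wm2 = round(rtnorm(n, 10.8 + cfg$wm2_shift * g2, 6.5, 0, Inf)),
    wm3 = round(rtnorm(n, 7.5 + cfg$wm3_shift * g2, 5.3, 0, Inf)),
    wm_time1 = round(rtnorm(n, 3.1, 1.9, 0.2, Inf), 2),
    wm_time2 = round(rtnorm(n, 2.0, 1.3, 0.2, Inf), 2),
    wm_time3 = round(rtnorm(n, 1.3 + cfg$wm_time3_shift * g2, 0.9, 0.2, Inf), 2),
    child_weekday_use = r_ordinal(n, c(0.55, 0.33, 0.11, 0.01)),
    child_weekend_use = r_ordinal(n, c(0.25, 0.40, 0.26, 0.09)),
    parent_weekday_use = r_ordinal(n, c(0.05, 0.15, 0.26, 0.54)),
    parent_weekend_use = r_ordinal(n, c(0.10, 0.30, 0.42, 0.18)),
    parent_age = round(rtnorm(n, 36.6, 5.1, 22, 55), 1),
    own_device = stats::runif(n) < 14 / 31,
    played_before = stats::runif(n) < 15 / 31,
    parent_education = ifelse(stats::runif(n) < 21 / 31, "higher", "secondary"),
    stringsAsFactors = FALSE)
}

#' Default pair of subgroup templates
#'
#' A segregated stochastic-block template (4 communities, p_within = 0.6,
#' p_between = 0.05) and an integrated uniform template matched to its
#' expected edge density.
#'
#' @param n_channels Channel count used to density-match the templates.
#' @param coupling_gain Planted-source amplitude for both templates.
#' @return Named list with elements `integrated` (subgroup 1) and
#'   `segregated` (subgroup 2).
#' @export
default_subgroup_specs <- function(n_channels = 19L, coupling_gain = 1) {
  seg <- subgroup_spec("segregated", 4L, 0.6, 0.05, coupling_gain)
  p <- expected_density(seg, n_channels)
  list(integrated = subgroup_spec("integrated", 1L, p, p, coupling_gain),
       segregated = seg)
}

#' Strong-contrast subgroup templates (positive-control regime)
#'
#' A sharper block structure (p_within = 0.9, p_between = 0.02) and a higher
#' planted-source amplitude than [default_subgroup_specs()]. Under these
#' templates the two subgroups are cleanly separable in graph-metric space,
#' which is the regime used to demonstrate end-to-end parameter recovery
#' against ground truth; the default templates are a harder, more realistic
#' contrast.
#'
#' @param n_channels Channel count used to density-match the templates.
#' @param coupling_gain Planted-source amplitude (default 2).
#' @return Named list with elements `integrated` and `segregated`.
#' @export
strong_contrast_specs <- function(n_channels = 19L, coupling_gain = 2) {
  seg <- subgroup_spec("segregated", 4L, 0.9, 0.02, coupling_gain)
  p <- expected_density(seg, n_channels)
  list(integrated = subgroup_spec("integrated", 1L, p, p, coupling_gain),
       segregated = seg)
}

#' Generate a full synthetic cohort with known ground truth
#'
#' Every participant receives a per-band coupling graph drawn from their
#' subgroup's template, and pre/post recordings that share this template
#' (the post recording is a fresh noise realization — the pre/post null
#' holds by construction), plus a behavioral record.
#'
#' @param n_participants Cohort size (>= 4).
#' @param subgroup_fraction Fraction assigned to subgroup 2 (segregated);
#'   the subgroup-2 count is `round(fraction * n)`.
#' @param effect_config Behavioral effect sizes, see [effect_config()].
#' @param n_channels,duration_s,rate_hz Recording geometry; defaults are a
#'   desk-scale 19-channel, 120-s, 256-Hz montage.
#' @param bands List of [band_spec()]s to plant coupling in.
#' @param coupling_gain Planted-source amplitude (used when `specs` is NULL).
#' @param noise Noise gains, see [synthesize_recording()].
#' @param specs Optional list of two [subgroup_spec()]s (subgroup 1 then 2);
#'   their expected densities must agree within 10%.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param make_recordings If `FALSE`, only labels and the behavioral table
#'   are generated (recordings list is empty) — useful for behavioral-only
#'   simulation studies.
#' @return An `eeg_cohort`: list with `recordings` (per participant, `$pre`
#'   and `$post`), `behavioral`, `labels`, `graphs`, `params`.
#' @export
generate_cohort <- function(n_participants = 31L, subgroup_fraction = 11 / 31,
                            effect_config = wplinet::effect_config(),
                            n_channels = 19L, duration_s = 120,
                            rate_hz = 256,
                            bands = default_bands()[c("delta", "beta")],
                            coupling_gain = 1,
                            noise = list(pink_gain = 1,
                                         zero_lag_mix_gain = 0.25),
                            specs = NULL, seed = 1L,
                            make_recordings = TRUE) {
  if (n_participants < 4L) stop("need n_participants >= 4")
  set.seed(seed)
  if (is.null(specs)) specs <- default_subgroup_specs(n_channels, coupling_gain)
  stopifnot(length(specs) == 2L)
  ref_density <- expected_density(specs[[1L]], n_channels)

  n2 <- round(subgroup_fraction * n_participants)
  labels <- sample(c(rep(1L, n_participants - n2), rep(2L, n2)))

  graphs <- vector("list", n_participants)
  recordings <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    gs <- lapply(bands, function(b)
      make_coupling_graph(specs[[labels[p]]], b, n_channels,
                          match_density = ref_density))
    names(gs) <- vapply(bands, function(b) b$name, "")
    graphs[[p]] <- gs
    if (make_recordings) {
      pid <- sprintf("P%02d", p)
      recordings[[p]] <- list(
        pre = synthesize_recording(gs, duration_s, rate_hz, noise,
                                   participant_id = pid, condition = "pre"),
        post = synthesize_recording(gs, duration_s, rate_hz, noise,
                                    participant_id = pid, condition = "post"))
    }
  }
  behavioral <- generate_behavioral(labels, effect_config)
  structure(list(recordings = recordings, behavioral = behavioral,
                 labels = labels, graphs = graphs,
                 params = list(n_participants = n_participants,
                               subgroup_fraction = subgroup_fraction,
                               n_channels = n_channels,
                               duration_s = duration_s, rate_hz = rate_hz,
                               bands = bands, coupling_gain = coupling_gain,
                               noise = noise, seed = seed)),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d participants (%d in subgroup 2), %d channels, %g s @ %g Hz; bands: %s\n",
              x$params$n_participants, sum(x$labels == 2L),
              x$params$n_channels, x$params$duration_s, x$params$rate_hz,
              paste(vapply(x$params$bands, function(b) b$name, ""),
                    collapse = ", ")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One file per participant x condition (`P<id>_<pre|post>.csv` or `.edf`),
#' a behavioral CSV, a ground-truth label CSV, and a JSON run manifest
#' recording seed and gains.
#'
#' @param cohort An `eeg_cohort` with recordings.
#' @param dir Output directory (created if missing).
#' @param format `"csv"` (delimited text) or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in seq_along(cohort$recordings)) {
    for (cond in c("pre", "post")) {
      rec <- cohort$recordings[[p]][[cond]]
      if (is.null(rec)) next
      fn <- file.path(dir, sprintf("P%02d_%s.%s", p, cond, format))
      if (format == "csv") write_recording_txt(rec, fn)
      else write_recording_edf(rec, fn)
    }
  }
  utils::write.csv(cohort$behavioral, file.path(dir, "behavioral.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(participant_id = cohort$behavioral$participant_id,
                              subgroup = cohort$labels),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  manifest <- cohort$params
  manifest$bands <- lapply(manifest$bands, unclass)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
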