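# Shared fixtures built in code at test time.

# Small deterministic cohort for pipeline/CLI smoke tests: 12 participants,
# 8 channels, 40 s. Cached per session.
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      specs <- list(
        integrated = subgroup_spec("integrated", 1, 0.3971429, 0.3971429, 2),
        segregated = subgroup_spec("segregated", 2, 0.9, 0.02, 2))
      cache <<- generate_cohort(
        n_participants = 12, subgroup_fraction = 0.5, n_channels = 8,
        duration_s = 40, rate_hz = 256,
        bands = default_bands()[c("delta", "beta")],
        specs = specs, seed = 11)   # seed chosen so no tiny binarized graph
                                    # is degree-regular (assortativity defined)
    }
    cache
  }
})

# small seeded recording with planted delta coupling
fixture_recording <- function(seed = 7, n_channels = 6, duration_s = 40,
                              gain = 2, zero_lag = 0) {
  set.seed(seed)
  spec <- subgroup_spec("segregated", 2, 0.9, 0.1, gain)
  g <- make_coupling_graph(spec, default_bands()$delta, n_channels)
  synthesize_recording(list(g), duration_s, 256,
                       noise = list(pink_gain = 1, zero_lag_mix_gain = zero_lag))
}
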