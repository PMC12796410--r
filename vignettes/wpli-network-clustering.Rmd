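---
title: "From resting-state EEG to wPLI network cluster profiles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From resting-state EEG to wPLI network cluster profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wplinet)
```

## The analysis in one paragraph

`wplinet` takes multichannel resting-state EEG recorded before and after an
intervention, estimates band-specific functional connectivity between all
electrode pairs with the weighted Phase Lag Index (wPLI), thresholds each
weighted network at a fixed edge density, and summarizes every
participant-condition network with five graph metrics: global efficiency,
local efficiency, clustering coefficient, node strength, and degree
assortativity. The resulting 10 features per participant and band (5 metrics
x pre/post) are z-scored and reduced to two principal components — with
Kaiser-Meyer-Olkin (KMO) and Bartlett sphericity diagnostics guarding
adequacy — then clustered hierarchically with Ward's method. Cluster counts
are profiled by elbow and silhouette curves, and the chosen solution is
validated by bootstrap Jaccard stability. Clusters are finally compared on
network and behavioral variables (Mann-Whitney U with rank-biserial
correlation; Fisher's exact test with phi), and partitions obtained in
different frequency bands are compared through a contingency table and the
Rand / adjusted Rand indices.

## Connectivity estimation

### Filtering

Band-pass filtering uses a linear-phase FIR filter (Hamming window design)
applied forward and backward, so the effective phase response is exactly
zero and the magnitude response is the squared FIR response. The transition
bandwidth at each band edge is `min(max(0.25 * edge, 2 Hz), edge)`: a
quarter of the edge frequency, floored at 2 Hz. The floor matters at low
edges — a strict 25% rule at a 0.5 Hz delta edge would require roughly
6,800 taps at 256 Hz and contaminate about 26 s at each end of a two-minute
recording with filter transient; with the 2 Hz floor the transient is about
6.6 s per side, and the squared response still attenuates one octave
outside the passband by far more than 20 dB. Edge regions are zero-padded;
the transient is therefore confined to the outermost epochs.

The default delta band is 0.5-4 Hz. A "below 4 Hz" definition and a
0.5-3.5 Hz variant are both in circulation; any variant can be requested
via `band_spec()`.

### Epoching and wPLI

Recordings are segmented into non-overlapping 4-second epochs (a trailing
remainder is discarded), giving 0.25 Hz spectral resolution. For each epoch
the package computes Hann-tapered DFTs and, for every channel pair, the
imaginary part of the cross-spectrum at every in-band frequency bin. The
wPLI is the pooled ratio

$$\mathrm{wPLI}_{ij} \;=\;
\frac{\bigl|\sum_k \mathrm{Im}\, S_{ij,k}\bigr|}
     {\sum_k \bigl|\mathrm{Im}\, S_{ij,k}\bigr|},$$

where \(k\) runs over all (epoch x in-band bin) cross-spectral samples. This
is the standard (not debiased) wPLI. Pooling epochs and bins into a single
ratio is one defensible reading of "averaged within the frequency band"; the
alternative (a per-bin ratio averaged across bins) has a larger small-sample
bias because each ratio then pools only the epochs. Pairs with a zero
denominator are assigned 0 — this includes the self-pairs and any pair
involving a zero-variance channel, which is retained (with a warning) rather
than dropped so that matrix shapes never change silently.

Because the statistic depends only on the *imaginary* part of the
cross-spectrum, signals mixed with zero phase lag — the signature of volume
conduction — contribute nothing systematic. Two caveats are worth knowing.
First, the estimator has a positive small-sample bias of order
\(1/\sqrt{M}\) for \(M\) pooled cross-spectral samples; in the delta band a
two-minute recording yields only 30 epochs x 15 bins = 450 samples, so the
"noise floor" for an uncoupled pair is roughly 0.05-0.1, while in beta
(69 bins) it is several times lower. Second, tapered neighboring bins are
correlated, which lowers the effective sample count further. Properties that
are exact statements about the formula (zero-lag insensitivity, the 0 and 1
endpoints) are therefore exercised in the test suite at high SNR and with
many pooled samples, where estimator noise cannot mask them.

## Graph metrics

The weighted matrix is binarized by retaining the `k = floor(density *
n(n-1)/2)` largest upper-triangle weights; `density = 0.2` by default. The
floor rule makes the edge count deterministic when `density * M` is not an
integer, and ties at the cutoff are broken by ascending (row, column) index
so the contract "exactly k edges" holds for any weight pattern.

Four metrics are computed on the binary graph: global efficiency (mean
inverse shortest-path length, disconnected pairs contributing 0), local
efficiency (mean over nodes of the global efficiency of the neighbor
subgraph; fewer than two neighbors contributes 0), mean clustering
coefficient (triangle fraction, degree < 2 contributing 0), and degree
assortativity (Pearson correlation of endpoint degrees over the directed
edge list). Node strength is computed on the *pre-threshold* weighted
matrix as the mean over nodes of incident weight sums. Assortativity of a
degree-regular graph is undefined and returned as a flagged `NA` rather
than a number; on very small montages (the 8-channel test fixture) regular
binarized graphs occur by chance, and the feature-assembly step treats the
flag as an error rather than imputing.

## Dimensionality reduction and clustering

Features are z-scored columnwise with the sample (n-1) standard deviation;
a constant column is an error naming the column. PCA is an
eigendecomposition of the feature correlation matrix; scores are the
standardized data projected on unit-norm loading vectors, and each
component's sign is fixed so its largest-magnitude loading is positive.
Exactly two components are extracted (the full explained-variance spectrum
is reported); pre and post features enter a single PCA jointly, so the
components can express both trait-like differences and pre/post
reconfiguration. KMO is computed from zero-order and partial correlations
(pseudo-inverse fallback, flagged, when the correlation matrix is
singular), Bartlett's sphericity statistic as
\(-(n - 1 - (2p + 5)/6)\ln|R|\) on \(p(p-1)/2\) degrees of freedom. The
package reports these diagnostics and leaves exclusion decisions (e.g.
dropping a band with KMO below 0.5) to the analyst.

Clustering uses Ward's minimum-variance criterion on Euclidean distances
(`hclust`, method `ward.D2`). The package deliberately does **not** choose
k: it emits inertia (elbow) and mean silhouette curves for `k_range` and
takes the reported k from configuration, because stability and
interpretability legitimately override the curves in small samples. Cluster
ids are canonicalized by descending size (ties: lowest member index), which
makes labels invariant to participant order.

### Bootstrap stability

For each of `n_boot = 300` iterations, `floor(0.8 n)` participants are
drawn *without replacement* (subsampling, not resampling), re-clustered
with the same method and k, and each reference cluster — restricted to the
subsample — is matched to the subsample cluster with maximal Jaccard index.
Per-cluster means are categorized with fixed bands: J >= 0.75 stable,
0.60-0.75 consistent, 0.50-0.60 unstable, below 0.50 dissolved; boundary
values go to the upper band. PC scores are held fixed across iterations:
the object being validated is the clustering solution, and refitting PCA
inside each iteration would confound component rotation with cluster
instability. An iteration that misses a reference cluster entirely records
J = 0 for it and is counted.

One empirical caution, visible in the test suite: an *arbitrary* Ward split
of a single homogeneous Gaussian blob is more reproducible under 80%
subsampling than intuition suggests (mean Jaccard typically 0.6-0.9). The
stability bands separate planted structure from no structure in
distribution — separated blobs sit near 1, arbitrary splits spread well
below — but a single "consistent" label on real data is weak evidence by
itself.

## Comparison statistics

Continuous variables are compared with a two-sided Mann-Whitney U test:
exact null distribution when `n1 * n2 <= 400` and no ties, otherwise the
normal approximation with tie and continuity corrections. The effect size
is the rank-biserial correlation \(r_{rb} = 2U_1/(n_1 n_2) - 1\) with
"group 1 = cluster 1", so a positive value means cluster 1 tends to exceed
cluster 2; published tables mix sign conventions, so the convention is
documented rather than reverse-engineered. Two-level categorical variables
get Fisher's exact test (two-sided by the probability-ordering rule) with
the signed phi coefficient; a zero margin is degenerate (p = 1, phi = 0,
flagged). Effect-size confidence intervals are seeded percentile bootstraps
(2000 resamples) — the interval method behind published CIs is rarely
stated, so these CIs are the package's own convention and are not expected
to reproduce any particular published interval. The paired pre/post
comparison uses the Wilcoxon signed-rank test with zero differences
dropped; for 25 or fewer nonzero differences the exact distribution is
computed by dynamic programming over (doubled) midranks, which unlike the
textbook exact path remains available under ties. Following the exploratory
design this package mirrors, **no multiple-comparison correction is
applied**, and output tables say so.

Partition agreement reports the contingency table, the Rand index, the
Hubert-Arabie (permutation-model) adjusted Rand index, and the number of
concordant participants after greedily matching clusters by maximal
overlap. If both partitions are trivial (single clusters), the ARI
denominator vanishes; the package defines ARI = 1 there, since the
partitions are then necessarily identical.

## The synthetic cohort

The package ships a generator that emulates the *structure* of a pre/post
pediatric resting-state cohort study: 31 participants
(11 in the second subgroup), two conditions sharing each participant's
coupling template (the pre/post null holds by construction), 2-minute
recordings at 256 Hz, and a behavioral table with the same schema
(working-memory trial scores and times, error counts, sex, ages, ordinal
0-3 device-use codes, device ownership, prior play, parental education).

Each participant receives a per-band coupling graph drawn from their
subgroup's template: a stochastic block model (4 communities, p_within =
0.6, p_between = 0.05 by default) for the "segregated" subgroup, and
density-matched uniform edges for the "integrated" subgroup — the subgroups
differ in topology, not edge count. Every edge carries a phase lag drawn
uniformly from [pi/8, 3*pi/8], strictly inside (0, pi) so wPLI can detect
it. Signals are band-limited Gaussian sources (ideally filtered white
noise, synthesized in the frequency domain with the lag applied as a
constant spectral rotation) shared between coupled channels, plus
per-channel 1/f background noise and a zero-lag common source standing in
for volume conduction. Pure sinusoids were deliberately avoided: they make
wPLI trivially 0 or 1 and would not exercise the estimator.

Defaults are desk-scale: 19 channels (the standard 10-20 montage), 120 s,
256 Hz; 62 channels are available via configuration. Behavioral effects
all live in one `effect_config()` object; defaults plant a working-memory
advantage of about 6 points (SD 6.5) on the second trial in the segregated
subgroup and a higher proportion of girls there, with device-use variables
independent of subgroup — magnitudes chosen once to be of the same order as
published cohort summaries of this design. `zero_effect_config()` switches
every planted effect off for null-calibration studies.

`strong_contrast_specs()` provides a sharper positive-control regime
(p_within = 0.9, p_between = 0.02, coupling gain 2) in which the two
subgroups are cleanly separable in graph-metric space; the end-to-end
recovery check in the test suite runs the full pipeline on ten such cohorts
(delta band, 19 channels, n = 31) and requires the k = 2 solution to reach
a mean adjusted Rand index of at least 0.6 against ground truth, with no
dissolved cluster. Under the default (harder) templates the per-participant
graph realization variance is large relative to the subgroup contrast, and
recovery is partial — a deliberate reminder that these metrics are noisy at
19 channels.

What the generator does *not* emulate: volume-conduction geometry from a
head model, electrode placement effects, artifacts (blinks, EMG, line
noise), non-stationarity across the recording, or any developmental
physiology. Passing the recovery tests therefore demonstrates that the
pipeline's inference machinery is sound, not that it would reach the same
conclusions on real pediatric EEG.

## Numerical conventions, in brief

- Seeds: every stochastic operation takes an explicit seed; cohorts,
  pipelines and bootstrap reports are bit-reproducible from (config, seed).
- wPLI matrices are clamped to [0, 1] and symmetrized exactly; the
  imaginary cross-spectrum is formed from real outer products so the
  diagonal is exactly zero even under fused-multiply-add contraction.
- Binarization ties: ascending (i, j) order; documented, deterministic.
- Efficiency conventions: 1/infinity = 0 for disconnected pairs; neighbor
  subgraphs with < 2 nodes contribute 0.
- Stability category boundaries are assigned upward (0.75 is "stable").
- Test problem sizes: module tests use 6-16-channel recordings of 16-240 s;
  the recovery check uses the full 19-channel, 120-s, n = 31 geometry; the
  type-I calibration uses 200 behavioral-only cohorts of n = 20.

## Limitations

The delta band at two minutes of recording provides few cross-spectral
samples, so individual wPLI entries carry a noise floor comparable to weak
true coupling; density thresholding partially absorbs this (ranks are more
stable than values), but metric variance at 19 channels remains
substantial. KMO/Bartlett diagnostics are computed on 31 x 10 tables where
n barely exceeds p; they are reported with that caveat rather than
suppressed. The bootstrap validates the clustering step only — it does not
propagate uncertainty from connectivity estimation or PCA. And the
comparison tables are exploratory by design: uncorrected p-values across
many variables will contain false positives at the nominal rate.
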