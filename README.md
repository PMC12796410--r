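# wplinet

Band-specific EEG functional connectivity with the weighted Phase Lag
Index, graph-theoretic network profiles, and cluster analysis of
participants — with a synthetic coupled-oscillator cohort generator so the
whole pipeline can be validated against known ground truth.

## Who this is for

Researchers analyzing multichannel resting-state EEG (e.g. pre/post an
intervention) who want to:

1. estimate **wPLI connectivity matrices** per frequency band — a phase
   coupling statistic insensitive to zero-lag (volume-conduction) mixing;
2. summarize each network with the five standard graph metrics after fixed
   **density thresholding** (top 20% of edges by default);
3. find **subgroups of participants** by PCA (with KMO / Bartlett adequacy
   diagnostics) followed by Ward hierarchical clustering, validated by
   **bootstrap Jaccard stability**;
4. compare subgroups on network and behavioral variables (Mann-Whitney U
   with rank-biserial effect size, Fisher exact with phi) and quantify
   **cross-band partition agreement** (Rand and adjusted Rand indices).

## The statistics at the core

For channels *i, j* and cross-spectral samples *S<sub>ij,k</sub>* pooled
over epochs and in-band DFT bins:

wPLI<sub>ij</sub> = |Σ<sub>k</sub> Im S<sub>ij,k</sub>| / Σ<sub>k</sub> |Im S<sub>ij,k</sub>|

Graph metrics on the density-thresholded binary graph: global efficiency
E<sub>glob</sub> = mean of 1/d<sub>ij</sub>, local efficiency
E<sub>loc</sub>, clustering coefficient C, degree assortativity r; node
strength s is computed on the weighted pre-threshold matrix. Partition
agreement uses RI = (a + b) / C(n,2) and the Hubert–Arabie ARI =
(Index − Expected) / (Max − Expected).

## Worked example

Generate a small synthetic cohort with two planted subgroups (one with
community-structured "segregated" coupling, one with density-matched
uniform coupling), run the delta-band pipeline, and compare the recovered
clusters with the ground truth:

```r
library(wplinet)

bands <- default_bands()[c("delta", "beta")]
co <- generate_cohort(n_participants = 12, subgroup_fraction = 0.5,
                      n_channels = 19, duration_s = 60, bands = bands,
                      specs = strong_contrast_specs(19), seed = 1)
#> <eeg_cohort> 12 participants (6 in subgroup 2), 19 channels, 60 s @ 256 Hz; bands: delta, beta

mets <- do.call(rbind, lapply(seq_along(co$recordings), function(p) rbind(
  graph_metrics(connectivity(co$recordings[[p]]$pre,  bands$delta)),
  graph_metrics(connectivity(co$recordings[[p]]$post, bands$delta)))))

pca <- pca2(zscore_features(feature_table(mets, "delta")))
#> <eeg_pca> 2 components: 55.5% + 15.5% of variance; KMO = 0.524;
#>           Bartlett chi2(45) = 125.51, p = 1.57e-09

sol <- ward_cluster(pca$scores, k_range = 2:5, k = 2)
st  <- bootstrap_stability(pca$scores, sol, n_boot = 300, frac = 0.8, seed = 1)
#> <stability_report> 300 bootstrap iterations, 80% subsampling
#>   cluster size mean_jaccard sd_jaccard category n_missed
#> 1       1    8    0.8753399  0.1301662   stable        0
#> 2       2    4    0.7826270  0.2330136   stable        0

partition_agreement(sol$labels, co$labels)
#> <partition_agreement> n = 12; RI = 0.697; ARI = 0.396; 10 concordant after matching
```

Reading the output: the two principal components carry 71% of the metric
variance and the KMO of 0.52 clears the conventional 0.5 adequacy floor;
both clusters are "stable" under subsampling (mean Jaccard ≥ 0.75); and
10 of 12 participants land in their true subgroup (at 60 s recordings the
delta-band wPLI estimates are still noisy — at the default 120 s the same
configuration recovers the planted subgroups essentially perfectly; the
test suite checks mean ARI ≥ 0.6 over ten 31-participant cohorts).

The full pipeline — simulation or reading recordings from disk, both bands,
comparisons and the cross-band agreement report, every artifact as CSV plus
a JSON run manifest — is one call:

```r
res <- run_pipeline(run_config(out_dir = "run1", simulate = TRUE,
                               sim = list(n_participants = 12), seed = 1))
```

A thin command-line front end with `simulate | connectivity | metrics |
cluster | compare | agreement | run` subcommands is installed at
`system.file("cli", "wplinet.R", package = "wplinet")`.

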