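# Cluster-profile comparison statistics and cross-band partition agreement.
#
# Significance threshold is p < 0.05 with NO multiple-comparison correction,
# mirroring an exploratory single-band workflow; output headers state this.

comparison_result <- function(variable, test, statistic, p_value,
                              effect_name, effect, ci = c(NA, NA),
                              summaries = NULL, flags = character()) {
  structure(list(variable = variable, test = test, statistic = statistic,
                 p_value = p_value, effect_name = effect_name,
                 effect_size = effect, effect_ci_low = ci[1L],
                 effect_ci_high = ci[2L], summaries = summaries,
                 flags = flags),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s, statistic = %.4g, p = %.4g, %s = %.3f (95%% CI %.3f, %.3f)%s\n",
              x$variable, x$test, x$statistic, x$p_value, x$effect_name,
              x$effect_size, x$effect_ci_low, x$effect_ci_high,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

# rank-biserial from two samples: r_rb = 2 U1 / (n1 n2) - 1,
# U1 = rank-sum wins of group 1 (midranks for ties)
rank_biserial <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u1 <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * u1 / (n1 * n2) - 1
}

#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-sided Mann-Whitney U with midranks for ties. The exact null
#' distribution is used when `n1 * n2 <= 400` and there are no ties;
#' otherwise the normal approximation with tie and continuity corrections.
#' The effect size is the rank-biserial correlation r_rb = 2 U1 / (n1 n2)
#' - 1 with group 1 = `x` (positive r_rb: `x` tends to exceed `y`); its 95%
#' CI is a seeded percentile bootstrap.
#'
#' @param x,y Nonempty numeric samples (group 1 and group 2).
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param seed Seed for the bootstrap.
#' @param variable Label carried into the result.
#' @return A `comparison_result`.
#' @export
mann_whitney_rb <- function(x, y, n_boot = 2000L, seed = 1L,
                            variable = "x vs y") {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 * n2 <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  rb <- rank_biserial(x, y)
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    rank_biserial(sample(x, n1, replace = TRUE),
                  sample(y, n2, replace = TRUE)), 0)
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  comparison_result(variable, "mann_whitney", unname(wt$statistic),
                    wt$p.value, "r_rb", rb, ci,
                    summaries = data.frame(
                      group = c(1L, 2L), n = c(n1, n2),
                      mean = c(mean(x), mean(y)),
                      sd = c(stats::sd(x), stats::sd(y))),
                    flags = if (exact) "exact" else "normal_approx")
}

#' Fisher's exact test with phi effect size on a 2x2 table
#'
#' Two-sided p by the probability-ordering rule (sum of hypergeometric
#' probabilities no larger than the observed table's). The effect size is
#' the signed phi coefficient (ad - bc) / sqrt of the margin product; its
#' 95% CI is a seeded percentile bootstrap over case resampling. A zero
#' margin is degenerate: p = 1, phi = 0, flagged.
#'
#' @param tab 2x2 matrix of nonnegative counts.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Seed for the bootstrap.
#' @param variable Label carried into the result.
#' @return A `comparison_result` (with `|phi|` available as
#'   `abs(effect_size)`).
#' @export
fisher_phi <- function(tab, n_boot = 2000L, seed = 1L, variable = "2x2") {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  n <- sum(tab)
  if (n < 1L) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(comparison_result(variable, "fisher_exact", NA_real_, 1,
                             "phi", 0, c(NA, NA), summaries = tab,
                             flags = "degenerate_margin"))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  phi <- (a * d - b * c) /
    sqrt(prod(c(rowSums(tab), colSums(tab))))
  p <- stats::fisher.test(tab)$p.value
  # case-resampling bootstrap on the underlying binary pairs
  rowv <- rep(c(1L, 1L, 2L, 2L), c(a, b, c, d))
  colv <- rep(c(1L, 2L, 1L, 2L), c(a, b, c, d))
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    tb <- table(factor(rowv[idx], 1:2), factor(colv[idx], 1:2))
    den <- prod(c(rowSums(tb), colSums(tb)))
    if (den == 0) return(0)
    (tb[1, 1] * tb[2, 2] - tb[1, 2] * tb[2, 1]) / sqrt(den)
  }, 0)
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  comparison_result(variable, "fisher_exact", NA_real_, p, "phi", phi, ci,
                    summaries = tab)
}

#' Paired pre/post Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of `post - pre` with zero differences
#' dropped; exact distribution for n <= 25 tie-free nonzero differences,
#' normal approximation with continuity correction otherwise. All-zero
#' differences are degenerate: p = 1, flagged. The effect size is the
#' matched-pairs rank-biserial correlation.
#'
#' @param pre,post Paired numeric samples of equal length.
#' @param variable Label carried into the result.
#' @return A `comparison_result`.
#' @export
wilcoxon_prepost <- function(pre, post, variable = "pre vs post") {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  dn <- d[d != 0]
  if (length(dn) == 0L)
    return(comparison_result(variable, "wilcoxon_signed_rank", NA_real_, 1,
                             "r_rb_matched", 0, c(NA, NA),
                             flags = "all_differences_zero"))
  nz <- length(dn)
  exact <- nz <= 25
  if (exact) {
    # exact null distribution of the signed-rank sum over all 2^n sign
    # assignments, with midranks for tied |differences|; computed by
    # dynamic programming on doubled (integer) ranks
    r2 <- as.integer(round(2 * rank(abs(dn))))
    counts <- c(1, rep(0, sum(r2)))      # counts[k + 1] = #assignments, V2 = k
    for (r in r2) {
      shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
      counts <- counts + shifted
    }
    v2 <- sum(r2[dn > 0])
    mu2 <- sum(r2) / 2
    support <- seq_along(counts) - 1
    p <- min(1, sum(counts[abs(support - mu2) >= abs(v2 - mu2) - 1e-9]) / 2^nz)
    v <- v2 / 2
  } else {
    wt <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    v <- unname(wt$statistic)
    p <- wt$p.value
  }
  tot <- nz * (nz + 1) / 2
  rb <- 2 * v / tot - 1                  # matched-pairs rank-biserial
  comparison_result(variable, "wilcoxon_signed_rank", v, p,
                    "r_rb_matched", rb,
                    flags = c(if (exact) "exact" else "normal_approx",
                              if (nz < length(d)) "zero_diffs_dropped"))
}

#' Agreement between two partitions: contingency, Rand and adjusted Rand
#'
#' RI = (a + b) / C(n, 2), with a = pairs co-clustered in both partitions
#' and b = pairs separated in both. ARI is the Hubert-Arabie
#' permutation-model form (Index - Expected) / (Max - Expected) with
#' Index = sum_ij C(n_ij, 2), Expected = sum_i C(a_i, 2) sum_j C(b_j, 2) /
#' C(n, 2), Max = (sum_i C(a_i, 2) + sum_j C(b_j, 2)) / 2. `n_concordant`
#' counts participants on the diagonal after greedily matching clusters by
#' maximal overlap. If both partitions are trivial (Max = Expected), ARI is
#' defined as 1 — they are then necessarily identical single-cluster
#' partitions.
#'
#' @param labels_a,labels_b Cluster label vectors over the same
#'   participants (same length and order).
#' @return A `partition_agreement`: `contingency`, `rand_index`,
#'   `adjusted_rand_index`, `n_concordant`, `n`, `pairs_both_together`,
#'   `pairs_both_apart`.
#' @export
partition_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions cover different participant sets")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  total <- choose(n, 2)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  a_pairs <- sum_ij
  b_pairs <- total + sum_ij - sum_a - sum_b
  ri <- (a_pairs + b_pairs) / total
  expected <- sum_a * sum_b / total
  mx <- (sum_a + sum_b) / 2
  ari <- if (abs(mx - expected) < 1e-12) 1 else (sum_ij - expected) / (mx - expected)
  # greedy maximal-overlap matching for the concordant count
  tb <- as.matrix(tab)
  conc <- 0
  while (nrow(tb) > 0L && ncol(tb) > 0L && max(tb) > 0) {
    idx <- which(tb == max(tb), arr.ind = TRUE)[1L, ]
    conc <- conc + tb[idx[1L], idx[2L]]
    tb <- tb[-idx[1L], -idx[2L], drop = FALSE]
  }
  structure(list(contingency = tab, rand_index = ri,
                 adjusted_rand_index = ari, n_concordant = as.integer(conc),
                 n = n, pairs_both_together = a_pairs,
                 pairs_both_apart = b_pairs),
            class = "partition_agreement")
}

#' @export
print.partition_agreement <- function(x, ...) {
  cat(sprintf("<partition_agreement> n = %d; RI = %.3f; ARI = %.3f; %d concordant after matching\n",
              x$n, x$rand_index, x$adjusted_rand_index, x$n_concordant))
  print(x$contingency)
  invisible(x)
}

#' Compare clusters on a set of variables (profile table)
#'
#' Continuous variables get a Mann-Whitney U test with rank-biserial effect
#' size; two-level categorical variables get Fisher's exact test with phi.
#' Cluster 1 is "group 1" for effect-size signs. No multiple-comparison
#' correction is applied; p-values are reported as-is for an exploratory
#' workflow.
#'
#' @param data Data frame of per-participant variables.
#' @param labels Cluster label vector (values 1 and 2).
#' @param continuous,categorical Character vectors naming columns of
#'   `data` to compare with each test family.
#' @param n_boot,seed Bootstrap settings for effect-size CIs.
#' @return A long `data.frame`: variable, per-cluster summaries, test,
#'   statistic, effect size and CI, p-value.
#' @export
compare_clusters <- function(data, labels, continuous,
                             categorical = character(), n_boot = 2000L,
                             seed = 1L) {
  stopifnot(nrow(data) == length(labels), all(labels %in% c(1L, 2L)))
  rows <- list()
  for (v in continuous) {
    x <- data[[v]][labels == 1L]; y <- data[[v]][labels == 2L]
    cr <- mann_whitney_rb(x, y, n_boot = n_boot, seed = seed, variable = v)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = cr$test,
      cluster1 = sprintf("%.2f ± %.2f", mean(x), stats::sd(x)),
      cluster2 = sprintf("%.2f ± %.2f", mean(y), stats::sd(y)),
      statistic = cr$statistic, effect_name = cr$effect_name,
      effect_size = cr$effect_size, ci_low = cr$effect_ci_low,
      ci_high = cr$effect_ci_high, p_value = cr$p_value,
      stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    f <- factor(data[[v]])
    if (nlevels(f) != 2L)
      stop(sprintf("categorical variable '%s' must have exactly 2 levels", v))
    tab <- table(f, factor(labels, 1:2))
    cr <- fisher_phi(tab, n_boot = n_boot, seed = seed, variable = v)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, test = cr$test,
      cluster1 = paste(sprintf("%s: %d", levels(f), tab[, 1L]),
                       collapse = ", "),
      cluster2 = paste(sprintf("%s: %d", levels(f), tab[, 2L]),
                       collapse = ", "),
      statistic = NA_real_, effect_name = cr$effect_name,
      effect_size = cr$effect_size, ci_low = cr$effect_ci_low,
      ci_high = cr$effect_ci_high, p_value = cr$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "note") <-
    "p < 0.05, two-sided; NO multiple-comparison correction applied"
  out
}

#' Paired pre/post comparison across all metric columns
#'
#' Runs [wilcoxon_prepost()] for every metric, pairing each participant's
#' pre and post values within one band.
#'
#' @param metrics Long metrics `data.frame` (see [graph_metrics()]).
#' @param band Band name to select.
#' @return Data frame with one row per metric: statistic, effect size,
#'   p-value.
#' @export
prepost_comparison <- function(metrics, band) {
  m <- metrics[metrics$band == band, , drop = FALSE]
  ids <- sort(unique(m$participant_id))
  cols <- c("global_efficiency", "local_efficiency",
            "clustering_coefficient", "node_strength", "assortativity")
  pre <- m[m$condition == "pre", ][match(ids, m$participant_id[m$condition == "pre"]), ]
  post <- m[m$condition == "post", ][match(ids, m$participant_id[m$condition == "post"]), ]
  do.call(rbind, lapply(cols, function(v) {
    cr <- wilcoxon_prepost(pre[[v]], post[[v]], variable = v)
    data.frame(variable = v, statistic = cr$statistic,
               effect_size = cr$effect_size, p_value = cr$p_value,
               stringsAsFactors = FALSE)
  }))
}
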