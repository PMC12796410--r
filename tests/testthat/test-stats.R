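test_that("rank-biserial hits its boundary and null values", {
  x <- c(1, 2, 3, 4)
  r0 <- mann_whitney_rb(x, x, n_boot = 50, seed = 1)
  expect_equal(r0$effect_size, 0)           # identical samples
  rs <- mann_whitney_rb(c(5, 6, 7), c(1, 2), n_boot = 50, seed = 1)
  expect_equal(rs$effect_size, 1)           # complete separation
  rr <- mann_whitney_rb(c(1, 2), c(5, 6, 7), n_boot = 50, seed = 1)
  expect_equal(rr$effect_size, -1)
  expect_error(mann_whitney_rb(numeric(0), x), "empty")
})

test_that("Mann-Whitney p matches exhaustive enumeration on small samples", {
  # the listed 2/3-sample example plus random tie-free cases
  o <- oracle_mw_enum(c(1, 3, 5), c(2, 4))
  w <- mann_whitney_rb(c(1, 3, 5), c(2, 4), n_boot = 50, seed = 1)
  expect_equal(w$statistic, o$u)
  expect_equal(w$p_value, o$p, tolerance = 1e-12)

  set.seed(13)
  for (rep in 1:30) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    repeat {
      x <- round(rnorm(n1, 0, 4), 3); y <- round(rnorm(n2, 1, 4), 3)
      if (anyDuplicated(c(x, y)) == 0) break
    }
    o <- oracle_mw_enum(x, y)
    w <- mann_whitney_rb(x, y, n_boot = 10, seed = 1)
    expect_equal(w$statistic, o$u)
    expect_equal(w$p_value, o$p, tolerance = 1e-12)
  }
})

test_that("U and r_rb follow direct pair counting even with ties", {
  set.seed(14)
  for (rep in 1:20) {
    x <- sample(0:5, sample(3:8, 1), replace = TRUE)
    y <- sample(0:5, sample(3:8, 1), replace = TRUE)
    wins <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    w <- mann_whitney_rb(x, y, n_boot = 10, seed = 1)
    expect_equal(w$statistic, wins)
    expect_equal(w$effect_size, 2 * wins / (length(x) * length(y)) - 1)
  }
})

test_that("swapping groups flips the sign of r_rb and keeps p", {
  set.seed(15)
  x <- rnorm(8); y <- rnorm(10, 1)
  a <- mann_whitney_rb(x, y, n_boot = 10, seed = 1)
  b <- mann_whitney_rb(y, x, n_boot = 10, seed = 1)
  expect_equal(a$effect_size, -b$effect_size, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("phi reproduces the sex-by-cluster association magnitude", {
  # girls/boys x cluster: (4, 16) in cluster 1, (7, 4) in cluster 2
  tab <- matrix(c(4, 16, 7, 4), 2, byrow = FALSE,
                dimnames = list(c("girl", "boy"), c("c1", "c2")))
  # laid out as rows = sex, cols = cluster: (4, 7) / (16, 4)
  tab <- matrix(c(4, 7, 16, 4), 2, byrow = TRUE)
  cr <- fisher_phi(tab, n_boot = 100, seed = 1)
  expect_equal(abs(cr$effect_size), 0.436, tolerance = 1e-3)  # printed precision
  expect_lt(cr$p_value, 0.05)

  diag5 <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_phi(diag5, n_boot = 50, seed = 1)$effect_size, 1)

  zm <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  dz <- fisher_phi(zm, n_boot = 50, seed = 1)
  expect_equal(dz$p_value, 1)
  expect_equal(dz$effect_size, 0)
  expect_true("degenerate_margin" %in% dz$flags)
})

test_that("Fisher p equals hypergeometric enumeration on small tables", {
  count <- 0
  for (n in 2:14) {
    parts <- expand.grid(a = 0:n, b = 0:n, c = 0:n)
    parts <- parts[rowSums(parts) <= n, ]
    parts$d <- n - rowSums(parts)
    for (i in seq_len(nrow(parts))) {
      tab <- matrix(unlist(parts[i, ]), 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p_enum <- oracle_fisher_enum(tab)
      p_r <- fisher.test(tab)$p.value
      if (abs(p_enum - p_r) > 1e-9)
        fail(sprintf("mismatch at table (%s): %g vs %g",
                     paste(tab, collapse = ","), p_enum, p_r))
      count <- count + 1
    }
  }
  expect_gt(count, 1500)                    # exhaustive small-table coverage
})

test_that("signed-rank test handles degenerate and shifted pairs", {
  pre <- c(3, 5, 2, 8, 1, 9, 4, 6, 7, 2.5)
  same <- wilcoxon_prepost(pre, pre)
  expect_equal(same$p_value, 1)
  expect_true("all_differences_zero" %in% same$flags)

  up <- wilcoxon_prepost(pre, pre + 1)      # constant positive shift, n = 10
  expect_equal(up$p_value, 2 / 2^10)        # minimal attainable two-sided p
  expect_equal(up$effect_size, 1)
})

test_that("signed-rank p matches exhaustive sign-flip enumeration at n = 10", {
  set.seed(16)
  for (rep in 1:15) {
    repeat {
      pre <- round(rnorm(10), 3); post <- round(pre + rnorm(10, 0.3), 3)
      d <- post - pre
      if (all(d != 0) && anyDuplicated(abs(d)) == 0) break
    }
    p_enum <- oracle_signrank_enum(d)
    w <- wilcoxon_prepost(pre, post)
    expect_equal(w$p_value, p_enum, tolerance = 1e-12)
  }
})

test_that("partition agreement reproduces the reference cross-band table", {
  la <- rep(c(1, 2), c(20, 11))
  lb <- c(rep(1, 18), rep(2, 2), rep(1, 7), rep(2, 4))
  ag <- partition_agreement(la, lb)
  expect_equal(as.vector(ag$contingency), c(18, 7, 2, 4))
  expect_equal(round(ag$rand_index, 3), 0.574)
  expect_equal(round(ag$adjusted_rand_index, 3), 0.132)
  expect_equal(ag$n_concordant, 22L)
  # pair bookkeeping implied by the Rand reproduction
  expect_equal(ag$pairs_both_together, 181)
  expect_equal(ag$pairs_both_apart, 86)
})

test_that("agreement indices satisfy their invariants", {
  la <- rep(c(1, 2), c(20, 11))
  lb <- c(rep(1, 18), rep(2, 2), rep(1, 7), rep(2, 4))
  ag <- partition_agreement(la, lb)
  swapped <- partition_agreement(lb, la)
  expect_equal(swapped$rand_index, ag$rand_index)
  expect_equal(swapped$adjusted_rand_index, ag$adjusted_rand_index)
  relab <- partition_agreement(3 - la, lb)  # relabeled clusters
  expect_equal(relab$adjusted_rand_index, ag$adjusted_rand_index)

  ident <- partition_agreement(la, la)
  expect_equal(ident$rand_index, 1)
  expect_equal(ident$adjusted_rand_index, 1)

  one <- partition_agreement(rep(1, 31), lb)
  expect_equal(one$adjusted_rand_index, 0)

  expect_error(partition_agreement(la, lb[-1]), "different participant")
})

test_that("RI/ARI match pair-counting and mclust oracles on random partitions", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(8:40, 1)
    a <- sample(1:sample(2:4, 1), n, replace = TRUE)
    b <- sample(1:sample(2:4, 1), n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    ag <- partition_agreement(a, b)
    o <- oracle_ri_ari(a, b)
    expect_equal(ag$rand_index, o$ri, tolerance = 1e-12)
    expect_equal(ag$adjusted_rand_index, o$ari, tolerance = 1e-12)
  }
  skip_if_not_installed("mclust")
  set.seed(18)
  for (rep in 1:10) {
    a <- sample(1:3, 25, replace = TRUE)
    b <- sample(1:3, 25, replace = TRUE)
    expect_equal(partition_agreement(a, b)$adjusted_rand_index,
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("cluster comparison table covers both test families", {
  set.seed(19)
  co <- generate_cohort(n_participants = 31, seed = 19,
                        make_recordings = FALSE)
  tab <- compare_clusters(co$behavioral, co$labels,
                          continuous = c("wm1", "wm2", "errors"),
                          categorical = c("sex", "own_device"),
                          n_boot = 100, seed = 1)
  expect_equal(nrow(tab), 5)
  expect_setequal(unique(tab$test), c("mann_whitney", "fisher_exact"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$effect_size >= -1 & tab$effect_size <= 1))
  expect_match(attr(tab, "note"), "NO multiple-comparison")
})

test_that("bootstrap effect-size CIs bracket the point estimate", {
  set.seed(20)
  x <- rnorm(15); y <- rnorm(15, 1.2)
  cr <- mann_whitney_rb(x, y, n_boot = 500, seed = 3)
  expect_lte(cr$effect_ci_low, cr$effect_size)
  expect_gte(cr$effect_ci_high, cr$effect_size)
  tab <- matrix(c(4, 7, 16, 4), 2, byrow = TRUE)
  cf <- fisher_phi(tab, n_boot = 500, seed = 3)
  expect_lte(cf$effect_ci_low, cf$effect_size)
  expect_gte(cf$effect_ci_high, cf$effect_size)
})
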