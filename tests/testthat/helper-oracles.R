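# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package: Floyd-Warshall instead of BFS,
# explicit triple/pair loops instead of matrix products, naive DFT sums
# instead of fft, exhaustive enumeration instead of closed forms.

oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a != 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_eff <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

oracle_local_eff <- function(a) {
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    vals[i] <- if (length(nb) < 2) 0 else
      oracle_global_eff(a[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    t <- 0
    for (u in seq_len(k - 1)) for (v in (u + 1):k)
      if (a[nb[u], nb[v]] != 0) t <- t + 1
    vals[i] <- 2 * t / (k * (k - 1))
  }
  mean(vals)
}

oracle_strength <- function(w) {
  n <- nrow(w)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + w[i, j]
  mean(s)
}

oracle_assortativity <- function(a) {
  deg <- sapply(seq_len(nrow(a)), function(i) sum(a[i, ] != 0))
  xs <- c(); ys <- c()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a)))
    if (i != j && a[i, j] != 0) { xs <- c(xs, deg[i]); ys <- c(ys, deg[j]) }
  if (length(xs) == 0) return(NULL)
  sx <- sqrt(mean(xs^2) - mean(xs)^2)
  sy <- sqrt(mean(ys^2) - mean(ys)^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  (mean(xs * ys) - mean(xs) * mean(ys)) / (sx * sy)
}

# wPLI by naive DFT sums over the same Hann-tapered epochs and band bins
oracle_wpli <- function(epochs, rate_hz, low_hz, high_hz) {
  L <- ncol(epochs[[1]])
  nch <- nrow(epochs[[1]])
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  kset <- c()
  for (k in 2:floor(L / 2)) {
    f <- (k - 1) * rate_hz / L
    if (f >= low_hz && f <= high_hz) kset <- c(kset, k)
  }
  num <- matrix(0, nch, nch); den <- matrix(0, nch, nch)
  tt <- 0:(L - 1)
  for (e in epochs) {
    for (k in kset) {
      basis <- exp(-2i * pi * (k - 1) * tt / L)
      X <- sapply(seq_len(nch), function(ch) sum(e[ch, ] * taper * basis))
      for (i in seq_len(nch)) for (j in seq_len(nch)) {
        im <- Im(X[i] * Conj(X[j]))
        num[i, j] <- num[i, j] + im
        den[i, j] <- den[i, j] + abs(im)
      }
    }
  }
  w <- abs(num) / den
  w[den == 0] <- 0
  diag(w) <- 0
  w
}

# exact two-sided Mann-Whitney p by enumerating group assignments
oracle_mw_enum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  combs <- utils::combn(n1 + n2, n1)
  u <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  p <- mean(abs(u - mu) >= abs(u_obs - mu) - 1e-9)
  list(u = u_obs, p = min(1, p))
}

# two-sided Fisher p by full hypergeometric enumeration
oracle_fisher_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided signed-rank p by enumerating all sign assignments
oracle_signrank_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9))
}

# exhaustive greedy Ward: at each step evaluate every merge's SSE increase
oracle_ward_partitions <- function(pts) {
  pts <- as.matrix(pts)
  clusters <- lapply(seq_len(nrow(pts)), identity)
  partitions <- list()
  partitions[[length(clusters)]] <- clusters
  while (length(clusters) > 1) {
    best <- NULL; best_inc <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ma <- colMeans(pts[a, , drop = FALSE])
        mb <- colMeans(pts[b, , drop = FALSE])
        inc <- length(a) * length(b) / (length(a) + length(b)) *
          sum((ma - mb)^2)
        if (inc < best_inc) { best_inc <- inc; best <- c(i, j) }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    partitions[[length(clusters)]] <- clusters
  }
  partitions
}

# cluster list -> label vector
partition_to_labels <- function(clusters, n) {
  lab <- integer(n)
  for (c in seq_along(clusters)) lab[clusters[[c]]] <- c
  lab
}

# KMO for exactly 3 features via explicit cofactor inversion
oracle_kmo3 <- function(x) {
  r <- cor(x)
  stopifnot(ncol(r) == 3)
  co <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    mi <- r[-i, -j, drop = FALSE]
    co[i, j] <- (-1)^(i + j) * (mi[1, 1] * mi[2, 2] - mi[1, 2] * mi[2, 1])
  }
  detr <- sum(r[1, ] * co[1, ])           # Laplace expansion, first row
  a <- t(co) / detr                       # inverse via adjugate
  q <- -a / sqrt(outer(diag(a), diag(a)))
  diag(q) <- 0
  r2 <- r^2; diag(r2) <- 0
  sum(r2) / (sum(r2) + sum(q^2))
}

# RI / ARI from explicit O(n^2) pair counting
oracle_ri_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  ri <- (n11 + n00) / (n11 + n00 + n10 + n01)
  ari <- 2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
  list(ri = ri, ari = ari)
}

# seeded random binary graph with at least one edge
random_graph <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.15, 0.7)
  repeat {
    a <- matrix(0L, n, n)
    ut <- which(upper.tri(a))
    a[ut] <- as.integer(runif(length(ut)) < p)
    a <- a + t(a)
    if (sum(a) > 0) return(a)
  }
}
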