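# Dimensionality reduction with adequacy diagnostics, Ward clustering,
# and bootstrap Jaccard stability.

#' Column-wise z-score standardization
#'
#' Uses the sample (n-1) standard deviation. Constant columns are an error
#' (they cannot be brought to unit variance).
#'
#' @param x Numeric matrix or data frame, participants x features.
#' @return Numeric matrix with column means 0 and sample SDs 1.
#' @export
zscore_features <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 participants")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant column(s): %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  scale(x)[, , drop = FALSE]
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall KMO = sum(r^2) / (sum(r^2) + sum(q^2)) over feature pairs, where
#' r are zero-order correlations and q are partial correlations
#' q_ij = -A_ij / sqrt(A_ii A_jj) with A the inverse of the correlation
#' matrix. When the correlation matrix is not invertible (e.g. fewer
#' observations than features) the Moore-Penrose pseudo-inverse is used and
#' the result is flagged with attribute `pseudo_inverse = TRUE` (with a
#' warning). Values below 0.5 are conventionally considered inadequate for
#' component analysis.
#'
#' @param x Numeric matrix, participants x features.
#' @return Overall KMO in \[0, 1\] with attribute `msa` (per-feature
#'   measures of sampling adequacy).
#' @export
kmo <- function(x) {
  x <- as.matrix(x)
  r <- stats::cor(x)
  p <- ncol(r)
  pseudo <- FALSE
  a <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(a) || nrow(x) <= p) {
    if (is.null(a)) {
      warning("correlation matrix not invertible; using pseudo-inverse")
      a <- MASS::ginv(r)
      pseudo <- TRUE
    } else if (nrow(x) <= p) {
      warning("fewer observations than features + 1; KMO may be unstable")
    }
  }
  q <- -a / sqrt(outer(diag(a), diag(a)))
  diag(q) <- 0
  r2 <- r^2; diag(r2) <- 0
  q2 <- q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  msa <- colSums(r2) / (colSums(r2) + colSums(q2))
  structure(overall, msa = msa, pseudo_inverse = pseudo)
}

#' Bartlett's test of sphericity
#'
#' Tests whether the feature correlation matrix is the identity:
#' chi^2 = -(n - 1 - (2p + 5)/6) * ln|R| on p(p-1)/2 degrees of freedom.
#'
#' @param x Numeric matrix, participants x features.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  r <- stats::cor(x)
  detr <- det(r)
  if (detr <= 0) stop("correlation matrix is singular (|R| <= 0)")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detr)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Two-component PCA on the feature correlation matrix
#'
#' Eigendecomposition of the correlation matrix of the (z-scored) feature
#' table. Scores are the standardized data projected on the unit-norm
#' loading vectors. Component signs are fixed so that each loading vector's
#' largest-magnitude entry is positive. KMO and Bartlett diagnostics are
#' computed alongside.
#'
#' @param x Numeric matrix, participants x features; it is z-scored
#'   internally (idempotent for already standardized input).
#' @return An `eeg_pca` object: `loadings` (features x 2), `scores`
#'   (participants x 2), `explained_variance_ratio` (full spectrum),
#'   `kmo`, `bartlett`.
#' @export
pca2 <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 features")
  if (nrow(x) < 3L) stop("need at least 3 participants")
  z <- zscore_features(x)
  r <- stats::cor(z)
  eig <- eigen(r, symmetric = TRUE)
  if (eig$values[2L] <= 1e-12)
    stop("feature matrix has rank < 2; a 2-component solution is degenerate")
  ratio <- eig$values / sum(eig$values)
  load <- eig$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- colnames(x)
  colnames(load) <- c("PC1", "PC2")
  scores <- z %*% load
  bart <- tryCatch(bartlett_sphericity(z), error = function(e)
    list(chi2 = NA_real_, df = ncol(z) * (ncol(z) - 1) / 2,
         p_value = NA_real_, note = conditionMessage(e)))
  structure(list(loadings = load, scores = scores,
                 explained_variance_ratio = ratio,
                 kmo = suppressWarnings(kmo(z)), bartlett = bart),
            class = "eeg_pca")
}

#' @export
print.eeg_pca <- function(x, ...) {
  cat(sprintf("<eeg_pca> 2 components: %.1f%% + %.1f%% of variance; KMO = %.3f; Bartlett chi2(%d) = %.2f, p = %.3g\n",
              100 * x$explained_variance_ratio[1L],
              100 * x$explained_variance_ratio[2L],
              as.numeric(x$kmo), x$bartlett$df, x$bartlett$chi2,
              x$bartlett$p_value))
  invisible(x)
}

# canonical relabeling: cluster ids by descending size, ties by lowest
# member index
relabel_by_size <- function(labels) {
  ids <- unique(labels)
  size <- vapply(ids, function(c) sum(labels == c), 0L)
  first <- vapply(ids, function(c) min(which(labels == c)), 0L)
  ord <- ids[order(-size, first)]
  match(labels, ord)
}

#' Hierarchical Ward clustering of PC scores with model-selection curves
#'
#' Builds the agglomerative tree with Ward's minimum-variance criterion on
#' Euclidean distances (`hclust`, `"ward.D2"`) and cuts it at every k in
#' `k_range`, recording within-cluster sum of squares (inertia, for the
#' elbow method) and mean silhouette width per k. Cluster ids are ordered
#' by descending size (ties: lowest member index), so labels are invariant
#' to participant order. k itself is chosen by the analyst (via `k`), not
#' automated.
#'
#' @param scores Numeric matrix, participants x components.
#' @param k_range Integer vector of cluster counts to profile (default 2:8).
#' @param k Cluster count for the reported labels (default 2).
#' @return A `cluster_solution`: `labels`, `k`, `tree`, `k_range`,
#'   `inertia_by_k`, `silhouette_by_k`, `labels_by_k`, `scores`.
#' @export
ward_cluster <- function(scores, k_range = 2:8, k = 2L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k_range <- k_range[k_range <= n]
  if (any(c(k_range, k) > n)) stop("k cannot exceed the number of participants")
  if (length(k_range) == 0L) stop("empty k_range after removing k > n")
  d <- stats::dist(scores)
  tree <- stats::hclust(d, method = "ward.D2")
  labels_by_k <- vapply(k_range, function(kk)
    relabel_by_size(stats::cutree(tree, kk)), integer(n))
  colnames(labels_by_k) <- paste0("k", k_range)
  inertia <- vapply(seq_along(k_range), function(ii) {
    lab <- labels_by_k[, ii]
    sum(vapply(unique(lab), function(c) {
      pts <- scores[lab == c, , drop = FALSE]
      sum(scale(pts, scale = FALSE)^2)
    }, 0))
  }, 0)
  sil <- vapply(seq_along(k_range), function(ii) {
    kk <- k_range[ii]
    if (kk < 2L || kk >= n) return(NA_real_)
    mean(cluster::silhouette(labels_by_k[, ii], d)[, "sil_width"])
  }, 0)
  labels <- relabel_by_size(stats::cutree(tree, k))
  structure(list(labels = labels, k = as.integer(k), tree = tree,
                 k_range = k_range, inertia_by_k = inertia,
                 silhouette_by_k = sil, labels_by_k = labels_by_k,
                 scores = scores),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d on %d participants; sizes: %s\n",
              x$k, length(x$labels),
              paste(table(x$labels), collapse = ", ")))
  cat("  k profiled:", paste(x$k_range, collapse = ", "), "\n")
  cat("  inertia:   ", paste(sprintf("%.2f", x$inertia_by_k), collapse = ", "), "\n")
  cat("  silhouette:", paste(sprintf("%.3f", x$silhouette_by_k), collapse = ", "), "\n")
  invisible(x)
}

#' Stability category from a mean Jaccard value
#'
#' Fixed bands, boundary values assigned to the upper band:
#' J >= 0.75 stable; 0.60 <= J < 0.75 consistent; 0.50 <= J < 0.60
#' unstable; J < 0.50 dissolved.
#'
#' @param j Mean Jaccard value(s) in \[0, 1\].
#' @return Character vector of categories.
#' @export
stability_category <- function(j) {
  cut(j, breaks = c(-Inf, 0.50, 0.60, 0.75, Inf), right = FALSE,
      labels = c("dissolved", "unstable", "consistent", "stable")) |>
    as.character()
}

#' Bootstrap Jaccard stability of a clustering solution
#'
#' For each of `n_boot` iterations, `floor(frac * n)` participants are drawn
#' without replacement, their PC scores re-clustered with the same method
#' and k, and each reference cluster (restricted to the subsample) is
#' matched to the subsample cluster maximizing the Jaccard index
#' J = |A n B| / |A u B|. PC scores are held fixed across iterations (the
#' solution, not the component rotation, is being validated). Iterations in
#' which a reference cluster is missing from the subsample are recorded as
#' J = 0 for that cluster and counted in `n_missed`.
#'
#' @param scores Participants x components score matrix.
#' @param reference A `cluster_solution` (k >= 2) or an integer label
#'   vector.
#' @param n_boot Number of iterations (default 300).
#' @param frac Subsample fraction (default 0.8).
#' @param seed Integer seed for the subsampling.
#' @param k Cluster count; taken from `reference` when it is a solution.
#' @return A `stability_report` data.frame: per cluster `mean_jaccard`,
#'   `sd_jaccard`, `category`, `n_missed`; attributes `n_boot`, `frac`.
#' @export
bootstrap_stability <- function(scores, reference, n_boot = 300L, frac = 0.8,
                                seed = 1L, k = NULL) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (inherits(reference, "cluster_solution")) {
    if (is.null(k)) k <- reference$k
    reference <- reference$labels
  }
  if (is.null(k)) k <- max(reference)
  if (k < 2L) stop("reference solution must have k >= 2")
  stopifnot(length(reference) == n, frac > 0, frac <= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- floor(frac * n)
  ref_sets <- lapply(seq_len(k), function(c) which(reference == c))
  jac <- matrix(0, n_boot, k)
  missed <- integer(k)
  for (it in seq_len(n_boot)) {
    idx <- sort(sample.int(n, m))
    sub_lab <- relabel_by_size(stats::cutree(
      stats::hclust(stats::dist(scores[idx, , drop = FALSE]),
                    method = "ward.D2"), k))
    sub_sets <- lapply(seq_len(max(sub_lab)), function(c) idx[sub_lab == c])
    for (c in seq_len(k)) {
      a <- intersect(ref_sets[[c]], idx)
      if (length(a) == 0L) { missed[c] <- missed[c] + 1L; next }  # J = 0
      jac[it, c] <- max(vapply(sub_sets, function(b)
        length(intersect(a, b)) / length(union(a, b)), 0))
    }
  }
  mj <- colMeans(jac)
  out <- data.frame(cluster = seq_len(k),
                    size = lengths(ref_sets),
                    mean_jaccard = mj,
                    sd_jaccard = apply(jac, 2L, stats::sd),
                    category = stability_category(mj),
                    n_missed = missed)
  structure(out, class = c("stability_report", "data.frame"),
            n_boot = n_boot, frac = frac)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d bootstrap iterations, %.0f%% subsampling\n",
              attr(x, "n_boot"), 100 * attr(x, "frac")))
  print.data.frame(x)
  invisible(x)
}
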