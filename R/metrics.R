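# Density thresholding and the five graph metrics.
#
# All metrics except node strength operate on the binary graph obtained by
# keeping the top `density` fraction of wPLI weights; node strength is
# computed on the weighted pre-threshold matrix.

#' Binarize a weighted connectivity matrix at fixed edge density
#'
#' Keeps the k = floor(density * n(n-1)/2) largest upper-triangle weights as
#' edges. Ties at the cutoff are broken by ascending (row, column) index
#' order, so the edge count is exactly k regardless of ties.
#'
#' @param w Symmetric nonnegative weight matrix (e.g. a
#'   `connectivity_matrix`).
#' @param density Fraction of possible edges to retain, in (0, 1);
#'   default 0.2.
#' @return Symmetric 0/1 adjacency matrix with zero diagonal and a
#'   `density` attribute.
#' @export
binarize_density <- function(w, density = 0.2) {
  w <- unclass(as.matrix(w))
  n <- nrow(w)
  if (n < 2L) stop("need at least 2 nodes")
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)")
  if (all(w[upper.tri(w)] == 0))
    stop("all-zero connectivity matrix: no rankable edges")
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  wt <- w[pairs]
  k <- floor(density * n * (n - 1) / 2)
  # stable sort: among equal weights the earlier (i, j) listing wins
  ord <- order(-wt, seq_along(wt))
  keep <- pairs[ord[seq_len(k)], , drop = FALSE]
  a <- matrix(0L, n, n, dimnames = dimnames(w))
  a[keep] <- 1L
  a[keep[, c(2L, 1L), drop = FALSE]] <- 1L
  attr(a, "density") <- density
  a
}

# BFS shortest-path distances from every source; Inf for unreachable
bfs_distances <- function(a) {
  n <- nrow(a)
  nbrs <- lapply(seq_len(n), function(i) which(a[i, ] != 0))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0L) {
      depth <- depth + 1L
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[d[s, nxt] == Inf]
      if (length(nxt) == 0L) break
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest-path length over all ordered node pairs; a
#' disconnected pair contributes 0 (the 1/infinity convention).
#'
#' @param a Symmetric 0/1 adjacency matrix.
#' @return Value in \[0, 1\].
#' @export
global_efficiency <- function(a) {
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 nodes")
  d <- bfs_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency of a binary graph
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's neighbors; nodes with fewer than 2 neighbors contribute 0.
#'
#' @param a Symmetric 0/1 adjacency matrix.
#' @return Value in \[0, 1\].
#' @export
local_efficiency <- function(a) {
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 nodes")
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] != 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(a[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

#' Mean clustering coefficient of a binary graph
#'
#' Mean over nodes of 2 t_i / (k_i (k_i - 1)), with t_i the number of
#' triangles through node i; nodes of degree < 2 contribute 0.
#'
#' @param a Symmetric 0/1 adjacency matrix.
#' @return Value in \[0, 1\].
#' @export
clustering_coefficient <- function(a) {
  if (nrow(a) < 1L) stop("empty graph")
  deg <- rowSums(a)
  a2 <- a %*% a
  tri <- diag(a2 %*% a) / 2
  ci <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  mean(ci)
}

#' Mean node strength of a weighted connectivity matrix
#'
#' Mean over nodes of the per-node sum of incident edge weights, computed on
#' the weighted matrix prior to thresholding.
#'
#' @param w Symmetric weight matrix.
#' @return Nonnegative scalar.
#' @export
node_strength <- function(w) {
  w <- unclass(as.matrix(w))
  mean(rowSums(w))
}

#' Degree assortativity of a binary graph
#'
#' Pearson correlation of endpoint degrees over the directed edge list (each
#' undirected edge counted in both orientations). Returns `NA` with
#' attribute `undefined = TRUE` when the endpoint degrees have zero variance
#' (e.g. a regular graph); an edgeless graph is an error.
#'
#' @param a Symmetric 0/1 adjacency matrix.
#' @return Value in \[-1, 1\], or flagged `NA`.
#' @export
assortativity <- function(a) {
  deg <- rowSums(a)
  e <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  if (nrow(e) == 0L) stop("assortativity undefined on an edgeless graph")
  x <- c(deg[e[, 1L]], deg[e[, 2L]])
  y <- c(deg[e[, 2L]], deg[e[, 1L]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, undefined = TRUE))
  stats::cor(x, y)
}

#' Compute the five graph metrics for one connectivity matrix
#'
#' @param w Weighted connectivity matrix (e.g. from [wpli()]).
#' @param density Edge density for binarization (default 0.2).
#' @return One-row `data.frame` with `global_efficiency`,
#'   `local_efficiency`, `clustering_coefficient`, `node_strength`,
#'   `assortativity` (plus `participant_id`, `condition`, `band` when the
#'   input carries them).
#' @export
graph_metrics <- function(w, density = 0.2) {
  a <- binarize_density(w, density)
  band <- attr(w, "band")
  data.frame(
    participant_id = as.character(attr(w, "participant_id") %||% NA),
    condition = as.character(attr(w, "condition") %||% NA),
    band = if (is.null(band)) NA_character_ else band$name,
    global_efficiency = global_efficiency(a),
    local_efficiency = local_efficiency(a),
    clustering_coefficient = clustering_coefficient(a),
    node_strength = node_strength(w),
    assortativity = as.numeric(assortativity(a)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wide 10-feature table for one band from a long metrics table
#'
#' Pivots the long per-participant/condition metric rows into the
#' participants x 10 feature layout used for dimensionality reduction, with
#' columns named `<Metric>_before` / `<Metric>_after` (pre maps to before).
#'
#' @param metrics Long `data.frame` as produced by row-binding
#'   [graph_metrics()] outputs.
#' @param band Band name to select.
#' @return Numeric matrix, participants x 10, rownames = participant ids.
#' @export
feature_table <- function(metrics, band) {
  m <- metrics[metrics$band == band, , drop = FALSE]
  if (nrow(m) == 0L) stop(sprintf("no metric rows for band '%s'", band))
  ids <- sort(unique(m$participant_id))
  cols <- c(global_efficiency = "Global_Efficiency",
            local_efficiency = "Local_Efficiency",
            clustering_coefficient = "Clustering_Coefficient",
            node_strength = "Node_Strength",
            assortativity = "Assortativity")
  out <- matrix(NA_real_, length(ids), 10L,
                dimnames = list(ids, c(paste0(cols, "_before"),
                                       paste0(cols, "_after"))))
  for (cond in c("pre", "post")) {
    suffix <- if (cond == "pre") "_before" else "_after"
    mm <- m[m$condition == cond, , drop = FALSE]
    rows <- match(mm$participant_id, ids)
    for (j in seq_along(cols))
      out[rows, paste0(cols[j], suffix)] <- mm[[names(cols)[j]]]
  }
  if (anyNA(out))
    stop("feature table has missing entries (incomplete participant/condition coverage or undefined assortativity)")
  out
}
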