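# Density-based clustering (DBSCAN) of 2D coordinates. Run on cluster
# points only; border points shape the embedding but are never clustered.

#' Density-based clustering of 2D coordinates
#'
#' Standard DBSCAN semantics: a core point has at least `min_pts` points
#' (itself included) within distance `eps`; clusters are the maximal
#' density-connected sets grown from core points; non-core points reachable
#' from no core point are noise. Cluster labels are deterministic: clusters
#' are numbered 1..K by their lowest member row index.
#'
#' Decreasing `min_pts` permits smaller clusters -- necessary when heavy
#' compression has thinned the point set, otherwise clusters are missed.
#'
#' @param coords Numeric n x 2 matrix of embedded cluster points (rownames =
#'   IDs).
#' @param min_pts Minimum neighbourhood size for a core point (>= 2).
#' @param eps Neighbourhood radius, or `"auto"` to use [estimate_eps()].
#' @return A list of class `cluster_labels`: `labels` (named integer vector;
#'   `-1` = noise), `k` (number of clusters), `min_pts`, `eps`.
#' @export
dbscan_cluster <- function(coords, min_pts = 20, eps = "auto") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(min_pts >= 2, n >= min_pts)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (identical(eps, "auto")) eps <- estimate_eps(coords, min_pts)
  stopifnot(is.numeric(eps), eps > 0)

  d <- as.matrix(stats::dist(coords))
  neighbours <- apply(d <= eps, 1L, which, simplify = FALSE)
  core <- lengths(neighbours) >= min_pts

  labels <- rep(-1L, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    k <- k + 1L
    labels[i] <- k
    frontier <- neighbours[[i]]
    while (length(frontier) > 0L) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (labels[j] == -1L) {
        labels[j] <- k
        if (core[j]) frontier <- c(frontier, neighbours[[j]][labels[neighbours[[j]]] == -1L])
      }
    }
  }
  if (k == 0L) {
    warning("no clusters found; consider decreasing minPts (", min_pts, ")")
  }
  structure(list(labels = stats::setNames(labels, ids), k = k,
                 min_pts = min_pts, eps = eps),
            class = "cluster_labels")
}

#' Estimate the DBSCAN neighbourhood radius
#'
#' The k-distance heuristic: returns the 95th percentile (type-7 quantile)
#' of the distribution of each point's distance to its (min_pts - 1)-th
#' nearest neighbour. Deterministic; scales linearly with the coordinates.
#'
#' @param coords Numeric matrix of coordinates.
#' @param min_pts The `min_pts` value the estimate is intended for.
#' @return A positive scalar radius.
#' @export
estimate_eps <- function(coords, min_pts = 20) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(n >= min_pts + 1)
  kd <- FNN::knn.dist(coords, k = min_pts - 1L)
  est <- unname(stats::quantile(kd[, min_pts - 1L], 0.95))
  if (est <= 0) {
    warning("degenerate coordinates (all k-distances zero); ",
            "falling back to a machine-epsilon-scaled radius")
    scale <- max(abs(coords), 1)
    est <- scale * sqrt(.Machine$double.eps)
  }
  est
}
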