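# Reversible point-set compression: randomly sampled representatives stand
# in for their nearest neighbours (associates) during embedding and
# clustering; decompression propagates representative labels back.

#' Compress a point set by random representative sampling
#'
#' Iteratively draws an unassigned point uniformly at random as a
#' representative and assigns its `c` nearest unassigned neighbours
#' (Euclidean distance in feature space, ties broken by lower row index) as
#' its associates, until every point is either a representative or an
#' associate. Only representatives are embedded and clustered, which reduces
#' the runtime of both steps; `c = 1` roughly halves the point count ("1NN").
#' `c = 0` disables compression (every point is a representative).
#'
#' @param features Numeric matrix, one row per point; rownames are point IDs.
#' @param c Compression factor (non-negative integer): maximum number of
#'   associates per representative.
#' @param seed RNG seed for the random sampling.
#' @return A list of class `compression_map`: `representatives` (ID vector),
#'   `assoc` (named vector associate ID -> representative ID), `c`, `seed`.
#' @export
compress_points <- function(features, c = 0, seed = 1) {
  stopifnot(is.matrix(features) || is.data.frame(features), c >= 0)
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(n >= 1)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  c <- as.integer(c)

  if (c == 0L) {
    cmap <- list(representatives = ids,
                 assoc = stats::setNames(character(0), character(0)),
                 c = 0L, seed = seed)
    class(cmap) <- "compression_map"
    return(cmap)
  }

  set.seed(seed)
  unassigned <- rep(TRUE, n)
  reps <- integer(0)
  assoc_to <- integer(n)   # 0 = not an associate
  while (any(unassigned)) {
    pool <- which(unassigned)
    r <- if (length(pool) == 1L) pool else sample(pool, 1L)
    unassigned[r] <- FALSE
    reps <- c(reps, r)
    pool <- which(unassigned)
    if (length(pool) > 0L) {
      d <- sqrt(colSums((t(features[pool, , drop = FALSE]) - features[r, ])^2))
      take <- pool[order(d, pool)][seq_len(min(c, length(pool)))]
      assoc_to[take] <- r
      unassigned[take] <- FALSE
    }
  }
  a <- which(assoc_to > 0L)
  cmap <- list(representatives = ids[reps],
               assoc = stats::setNames(ids[assoc_to[a]], ids[a]),
               c = c, seed = seed)
  class(cmap) <- "compression_map"
  cmap
}

#' Propagate representative labels to their associates (decompression)
#'
#' Each associate inherits the de novo cluster label of its representative;
#' representatives keep their own labels. This recovers a label for every
#' compressed point and enlarges the classifier training set beyond the
#' sampled representatives alone.
#'
#' @param cmap A `compression_map` from [compress_points()].
#' @param rep_labels Named vector mapping representative ID to cluster label
#'   (noise, `-1`, is a legal label).
#' @return Named vector mapping every point ID (representatives and
#'   associates) to a label.
#' @export
decompress_labels <- function(cmap, rep_labels) {
  stopifnot(inherits(cmap, "compression_map"))
  missing <- setdiff(cmap$representatives, names(rep_labels))
  if (length(missing) > 0L) {
    stop("unlabeled representative(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  out <- rep_labels[cmap$representatives]
  names(out) <- cmap$representatives
  if (length(cmap$assoc) > 0L) {
    inherited <- rep_labels[unname(cmap$assoc)]
    names(inherited) <- names(cmap$assoc)
    out <- c(out, inherited)
  }
  out
}
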