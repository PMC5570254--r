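# 2D embedding of signature vectors by Barnes-Hut t-SNE.

#' Embed feature vectors in 2D
#'
#' Computes a nonlinear, neighbourhood-preserving 2D embedding of the
#' (border + cluster point) signature vectors with Barnes-Hut t-SNE,
#' preceded by a PCA reduction to at most `initial_dims` dimensions for
#' speed and stability. The embedding is stochastic but fully determined by
#' `seed`.
#'
#' @param features Numeric matrix, one row per point; rownames are IDs.
#' @param perplexity t-SNE perplexity; clamped to (n - 1)/3 with a warning
#'   when too large for the point count.
#' @param seed RNG seed.
#' @param theta Barnes-Hut accuracy/speed trade-off (0 = exact).
#' @param max_iter Number of gradient iterations.
#' @param initial_dims PCA pre-reduction dimensionality.
#' @return A list of class `embedding_2d`: `ids`, `coords` (n x 2 matrix,
#'   rownames = IDs), `perplexity`, `seed`.
#' @export
embed_2d <- function(features, perplexity = 30, seed = 1, theta = 0.5,
                     max_iter = 1000, initial_dims = 50) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 4) stop("too few points to embed (n = ", n, ", need >= 4)")
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  max_perp <- (n - 1) / 3
  if (perplexity >= max_perp) {
    perplexity <- max(1, floor(max_perp - 1e-9))
    warning("perplexity too large for ", n, " points; clamped to ",
            perplexity)
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                      theta = theta, max_iter = max_iter,
                      pca = TRUE, partial_pca = FALSE,
                      initial_dims = min(initial_dims, ncol(features)),
                      check_duplicates = FALSE, verbose = FALSE,
                      num_threads = 1)
  coords <- fit$Y
  rownames(coords) <- ids
  colnames(coords) <- c("x", "y")
  structure(list(ids = ids, coords = coords, perplexity = perplexity,
                 seed = seed),
            class = "embedding_2d")
}
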