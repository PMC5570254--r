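# The supervised half of bootstrapped supervised binning: a random forest
# trained on de novo cluster labels (decompressed to associates) over
# signature features assigns every retained sequence a final bin.
#
# Clusters and bins are distinct layers: a cluster is an intermediate
# sequence set found on the cluster points only; a bin is the final set
# after the classifier has labelled every sequence >= min_len.

#' Assemble the classifier training set
#'
#' The training set consists of every non-noise cluster point together with
#' its decompressed associates, which inherit the representative's cluster
#' label. Noise points and border points contribute no training rows.
#' Features are the (transformed) genomic signatures: signature space is the
#' only space shared by all sequences, including the short "remaining"
#' points that are never embedded.
#'
#' @param clusters A `cluster_labels` object over the cluster-point
#'   representatives.
#' @param cmap A `compression_map` (or `NULL` when compression was off).
#' @param features Transformed signature matrix covering at least all
#'   training IDs (rownames = IDs).
#' @return A list with `x` (feature matrix) and `y` (factor of cluster
#'   labels).
#' @export
build_training_set <- function(clusters, cmap, features) {
  stopifnot(inherits(clusters, "cluster_labels"))
  rep_labels <- clusters$labels
  keep_reps <- names(rep_labels)[rep_labels != -1L]
  train_labels <- rep_labels[keep_reps]
  if (!is.null(cmap) && length(cmap$assoc) > 0L) {
    of_kept <- names(cmap$assoc)[unname(cmap$assoc) %in% keep_reps]
    if (length(of_kept) > 0L) {
      inherited <- rep_labels[unname(cmap$assoc[of_kept])]
      names(inherited) <- of_kept
      train_labels <- c(train_labels, inherited)
    }
  }
  if (length(train_labels) == 0L) {
    stop("no clusters to learn from: all cluster points are noise; ",
         "consider decreasing minPts")
  }
  missing <- setdiff(names(train_labels), rownames(features))
  if (length(missing) > 0L)
    stop("training IDs absent from feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  list(x = features[names(train_labels), , drop = FALSE],
       y = factor(unname(train_labels)))
}

#' Train the random forest and assign final bins
#'
#' Fits a seeded random-forest classifier on the training set and predicts a
#' bin for every sequence of length >= `min_len` -- cluster, border,
#' remaining and noise points alike. Training sequences are re-predicted, so
#' a sequence's bin may differ from its de novo cluster. Bin labels are a
#' subset of the cluster labels: the classifier cannot invent classes.
#'
#' @param training List from [build_training_set()].
#' @param features Transformed signature matrix for all sequences to bin
#'   (rownames = IDs).
#' @param roles Named role vector from [assign_roles()] covering the feature
#'   rows.
#' @param min_len Minimum length for binning (bp); sequences below it are
#'   discarded.
#' @param lengths Named vector of sequence lengths (bp).
#' @param seed RNG seed for the forest.
#' @param n_trees Number of trees, default 500.
#' @return A list of class `binning_result`: `bin` (named vector ID -> bin
#'   label for all retained sequences), `k_bins`, `n_train`, `seed`.
#' @export
train_and_assign <- function(training, features, roles, lengths,
                             min_len = 500, seed = 1, n_trees = 500) {
  retained <- names(roles)[roles != "discarded" & lengths[names(roles)] >= min_len]
  retained <- intersect(rownames(features), retained)
  if (length(retained) == 0L) stop("no sequences retained for binning")
  if (nlevels(training$y) < 2L) {
    warning("only one cluster found; assigning all retained sequences to it")
    bin <- stats::setNames(rep(as.integer(as.character(levels(training$y))),
                               length(retained)), retained)
    res <- list(bin = bin, k_bins = 1L, n_train = nrow(training$x),
                seed = seed)
    class(res) <- "binning_result"
    return(res)
  }
  stopifnot(ncol(training$x) == ncol(features))
  set.seed(seed)
  forest <- randomForest::randomForest(x = training$x, y = training$y,
                                       ntree = n_trees)
  pred <- stats::predict(forest, features[retained, , drop = FALSE])
  bin <- stats::setNames(as.integer(as.character(pred)), retained)
  res <- list(bin = bin, k_bins = length(unique(bin)),
              n_train = nrow(training$x), seed = seed)
  class(res) <- "binning_result"
  res
}

#' Aggregate chunk-level bins to their parent sequences
#'
#' In chunked mode the whole pipeline operates on chunks; each parent contig
#' is then assigned the bin that received the largest total chunk length
#' (majority vote by bp), ties broken by the smaller bin label. The per-
#' parent agreement fraction (bp in the winning bin / total binned bp)
#' quantifies how unanimous the chunks were.
#'
#' @param bins Named vector chunk ID -> bin label.
#' @param chunk_map List from [chunk_sequences()].
#' @param chunk_lengths Named vector of chunk lengths (bp).
#' @return A list with `bin` (named vector parent ID -> bin label; parents
#'   with zero retained chunks are absent, i.e. unbinned) and `agreement`
#'   (named numeric vector in [0, 1]).
#' @export
aggregate_chunk_bins <- function(bins, chunk_map, chunk_lengths) {
  parents <- unique(unname(chunk_map$parent))
  out_bin <- integer(0)
  out_agr <- numeric(0)
  binned_parent <- chunk_map$parent[names(bins)]
  for (p in parents) {
    ch <- names(binned_parent)[binned_parent == p]
    if (length(ch) == 0L) next   # parent unbinned
    w <- tapply(chunk_lengths[ch], bins[ch], sum)
    best <- sort(as.integer(names(w)[w == max(w)]))[1]
    out_bin[p] <- best
    out_agr[p] <- unname(w[as.character(best)] / sum(w))
  }
  list(bin = out_bin, agreement = out_agr)
}
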