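# Ground truth-based scoring: per-genome sensitivity, per-bin precision,
# and their harmonic mean (F1), aggregated over genomes.

#' Score a binning result against ground truth
#'
#' For each source genome g, the best bin is the bin containing the largest
#' (bp-weighted by default) share of g. Then:
#' \itemize{
#'   \item sensitivity(g) = weight of g inside its best bin / total weight
#'     of g among the binned sequences;
#'   \item precision(b) = weight of b's majority genome / total weight of b
#'     (bin purity);
#'   \item F1(g) = harmonic mean of sensitivity(g) and precision(best bin
#'     of g).
#' }
#' All metrics are reported in percent. bp-weighting is the default because
#' binning quality is about the fraction of a genome recovered, not the
#' number of fragments; `weight = "count"` treats every sequence equally
#' (useful for chunk-level scoring).
#'
#' By default, sequences the binner never claimed (discarded by the length
#' cutoff, or left unbinned) are excluded from the sensitivity denominator;
#' `strict = TRUE` counts them against sensitivity.
#'
#' @param bins Named vector sequence ID -> bin label, or a `binning_result`.
#' @param truth Named vector sequence ID -> source genome label.
#' @param lengths Named vector of sequence lengths (bp); required for
#'   `weight = "bp"`.
#' @param weight `"bp"` (default) or `"count"`.
#' @param strict Include unbinned truth sequences in the sensitivity
#'   denominator.
#' @return A list of class `evaluation_table`: `per_genome` (data frame:
#'   genome, best_bin, sensitivity, precision, f1), `summary` (mean/median
#'   of each metric, in percent), `k_bins`.
#' @export
score_binning <- function(bins, truth, lengths = NULL,
                          weight = c("bp", "count"), strict = FALSE) {
  weight <- match.arg(weight)
  if (inherits(bins, "binning_result")) bins <- bins$bin
  shared <- intersect(names(bins), names(truth))
  if (length(shared) == 0L)
    stop("no sequence ID is present in both the binning result and the ",
         "ground truth")
  w <- if (weight == "bp") {
    if (is.null(lengths)) stop("'lengths' required for bp-weighted scoring")
    lengths
  } else {
    stats::setNames(rep(1, length(truth)), names(truth))
  }

  tab <- data.frame(id = shared,
                    bin = as.character(bins[shared]),
                    genome = as.character(truth[shared]),
                    w = as.numeric(w[shared]),
                    stringsAsFactors = FALSE)
  # weight of each (genome, bin) pair among binned sequences
  cross <- tapply(tab$w, list(tab$genome, tab$bin), sum, default = 0)
  genome_binned <- rowSums(cross)
  bin_total <- colSums(cross)
  precision_bin <- apply(cross, 2L, max) / bin_total * 100

  genomes <- rownames(cross)
  genome_total <- if (strict) {
    all_truth <- tapply(as.numeric(w[names(truth)]), as.character(truth),
                        sum)
    all_truth[genomes]
  } else {
    genome_binned
  }

  best_bin <- colnames(cross)[max.col(cross, ties.method = "first")]
  best_w <- cross[cbind(genomes, best_bin)]
  sensitivity <- best_w / genome_total * 100
  precision <- precision_bin[best_bin]
  f1 <- ifelse(sensitivity + precision > 0,
               2 * sensitivity * precision / (sensitivity + precision), 0)

  per_genome <- data.frame(genome = genomes, best_bin = best_bin,
                           sensitivity = unname(sensitivity),
                           precision = unname(precision),
                           f1 = unname(f1),
                           stringsAsFactors = FALSE)
  summary <- c(mean_sensitivity = mean(per_genome$sensitivity),
               median_sensitivity = stats::median(per_genome$sensitivity),
               mean_precision = mean(per_genome$precision),
               median_precision = stats::median(per_genome$precision),
               mean_f1 = mean(per_genome$f1),
               median_f1 = stats::median(per_genome$f1))
  structure(list(per_genome = per_genome, summary = summary,
                 k_bins = length(unique(tab$bin))),
            class = "evaluation_table")
}

#' @export
print.evaluation_table <- function(x, ...) {
  cat("Binning evaluation over", nrow(x$per_genome), "genomes,",
      x$k_bins, "bins\n")
  print(x$per_genome, row.names = FALSE, digits = 4)
  cat("\n")
  print(round(x$summary, 2))
  invisible(x)
}
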