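# Genomic signatures: canonical oligonucleotide frequency vectors.
# Strands are pooled (a k-mer and its reverse complement are one feature)
# because contig orientation is arbitrary in an assembly.

#' All canonical k-mers, in lexicographic order
#'
#' A k-mer is "canonical" if it is the lexicographic minimum of itself and its
#' reverse complement. For odd k there are 4^k/2 canonical k-mers (no k-mer is
#' its own reverse complement); for even k, 4^k/2 + 4^(k/2)/2 (palindromes).
#'
#' @param k Oligonucleotide length (1--8).
#' @return Character vector of canonical k-mers, sorted.
#' @export
canonical_kmers <- function(k) {
  stopifnot(k >= 1, k <= 8)
  all_k <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  sort(unique(canonical_kmer(all_k)))
}

#' Canonicalize k-mers
#'
#' Maps each k-mer to the lexicographic minimum of itself and its reverse
#' complement. Idempotent. K-mers containing characters outside A/C/G/T
#' (ambiguity codes) return `NA`, signalling "skip this window".
#'
#' @param kmer Character vector of same-length DNA k-mers.
#' @return Character vector of canonical k-mers (`NA` where ambiguous).
#' @export
canonical_kmer <- function(kmer) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(chartr("RYSWKMBDHVN", "NNNNNNNNNNN", kmer))))
  out <- ifelse(kmer <= rc, kmer, rc)
  out[grepl("[^ACGT]", kmer)] <- NA_character_
  out
}

#' Canonical k-mer frequency signatures
#'
#' Computes, for each sequence, the frequency vector of canonical k-mers over
#' all sliding windows of length k that consist solely of A/C/G/T. Windows
#' containing N or other ambiguity codes are skipped. Counts are divided by
#' the number of counted ("valid") windows so each row sums to 1; a sequence
#' with no valid window gets a zero row and is flagged.
#'
#' @param x A data frame with `id` and `seq` columns (see [read_fasta()]), or
#'   a character vector of sequences (optionally named).
#' @param k Oligonucleotide length; pentamers (k = 5, 512 features) by
#'   default.
#' @return A numeric matrix, one row per sequence (rownames = IDs), one
#'   column per canonical k-mer, with attributes `k` and `windows` (valid
#'   window count per row).
#' @export
kmer_signatures <- function(x, k = 5) {
  stopifnot(k %in% 3:6)
  if (is.data.frame(x)) {
    seqs <- stats::setNames(x$seq, x$id)
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  }
  if (any(nchar(seqs) < k))
    stop("sequence shorter than k (", k, " bp): ",
         names(seqs)[which(nchar(seqs) < k)[1]])
  dss <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(dss, width = k, step = 1)
  canon <- canonical_kmer(colnames(counts))
  feats <- canonical_kmers(k)
  # pool each k-mer column into its canonical feature
  pool <- matrix(0, nrow = nrow(counts), ncol = length(feats),
                 dimnames = list(names(seqs), feats))
  idx <- match(canon, feats)
  for (j in seq_along(idx)) {
    pool[, idx[j]] <- pool[, idx[j]] + counts[, j]
  }
  w <- rowSums(counts)
  freq <- pool / ifelse(w > 0, w, 1)
  if (any(w == 0)) {
    warning(sum(w == 0), " sequence(s) had no valid k-mer window ",
            "(all windows contain ambiguity codes); zero signature assigned")
  }
  structure(freq, k = k, windows = w)
}

#' Transform a signature matrix for embedding and classification
#'
#' The default is a centered log-ratio (CLR) transform: k-mer frequencies are
#' compositional, and log-ratio geometry tends to separate genome-specific
#' signatures better than raw frequencies. A pseudo-frequency of 1/(2W) per
#' component (W = number of valid windows of the row, floored at 1e-6) avoids
#' log(0) and shrinks with sequence length, so long sequences are barely
#' perturbed.
#'
#' @param sig Matrix from [kmer_signatures()].
#' @param method `"clr"` (default) or `"none"` (identity).
#' @return Matrix of the same shape; CLR rows have zero mean. Zero-window
#'   rows are left as zeros and listed in the `untransformed` attribute.
#' @export
transform_signatures <- function(sig, method = c("clr", "none")) {
  method <- match.arg(method)
  if (method == "none") return(sig)
  w <- attr(sig, "windows")
  if (is.null(w)) w <- rep(1, nrow(sig))
  pseudo <- pmax(1 / (2 * pmax(w, 1e-6)), 1e-6)
  out <- sig
  ok <- w > 0
  if (any(ok)) {
    lp <- log(sig[ok, , drop = FALSE] + pseudo[ok])
    out[ok, ] <- lp - rowMeans(lp)
  }
  structure(out, k = attr(sig, "k"), windows = w,
            untransformed = rownames(sig)[!ok])
}
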