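# Size selection into point roles, and fixed-length chunking of long
# sequences for cluster-density normalization.

#' Assign point roles by sequence length
#'
#' Size-selects sequences into the four roles the binning pipeline
#' distinguishes:
#' \describe{
#'   \item{cluster}{length >= t_c; embedded and clustered de novo.}
#'   \item{border}{t_b <= length < t_c; embedded to push clusters apart, but
#'     never clustered.}
#'   \item{remaining}{min_len <= length < t_b; neither embedded nor
#'     clustered, binned only by the trained classifier.}
#'   \item{discarded}{length < min_len; excluded entirely.}
#' }
#' Each lower edge is inclusive. Setting `t_b = t_c` (a useful configuration
#' for narrow length distributions, e.g. `t_b = t_c = 500` for raw long
#' reads) produces no border points.
#'
#' @param records Data frame with `id` and `length` columns, or a numeric
#'   vector of lengths (optionally named).
#' @param t_b Border-point length threshold (bp), default 1000.
#' @param t_c Cluster-point length threshold (bp), default 1000.
#' @param min_len Minimum retained length (bp), default 500.
#' @return Named character vector of roles, one per sequence.
#' @export
assign_roles <- function(records, t_b = 1000, t_c = 1000, min_len = 500) {
  if (is.data.frame(records)) {
    len <- stats::setNames(records$length, records$id)
  } else {
    len <- records
  }
  if (t_b > t_c) {
    stop("t_b (", t_b, ") must not exceed t_c (", t_c,
         "); consider decreasing t_c to the value of t_b")
  }
  if (min_len > t_b) {
    stop("min_len (", min_len, ") must not exceed t_b (", t_b, ")")
  }
  role <- ifelse(len >= t_c, "cluster",
          ifelse(len >= t_b, "border",
          ifelse(len >= min_len, "remaining", "discarded")))
  stats::setNames(role, names(len))
}

#' Split sequences into fixed-length chunks
#'
#' Cuts each sequence into consecutive, non-overlapping windows of
#' `chunk_length` bp. A final remainder shorter than `min_len` is merged into
#' the preceding chunk (so no fragment of a long contig is ever discarded);
#' sequences shorter than `chunk_length` become a single chunk. Chunking
#' normalizes cluster-point density: the number of points per genome then
#' reflects genome length rather than contig count.
#'
#' @param records Data frame with `id`, `seq`, `length`.
#' @param chunk_length Window size (bp), default 3000.
#' @param min_len Minimum retained length (bp), default 500.
#' @return A list with `chunks` (data frame `id`, `seq`, `length`, `parent`,
#'   `offset`; chunk IDs are `<parent>|chunk<i>`) and `parent` (named vector
#'   chunk ID -> parent ID).
#' @export
chunk_sequences <- function(records, chunk_length = 3000, min_len = 500) {
  stopifnot(chunk_length >= min_len)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    len <- records$length[i]
    full <- len %/% chunk_length
    rem <- len %% chunk_length
    n_chunks <- if (full == 0L) 1L else if (rem >= min_len) full + 1L else full
    starts <- seq.int(1L, by = chunk_length, length.out = n_chunks)
    ends <- pmin(starts + chunk_length - 1L, len)
    ends[length(ends)] <- len   # merge a short tail into the final chunk
    id <- records$id[i]
    out[[i]] <- data.frame(
      id = paste0(id, "|chunk", seq_along(starts)),
      seq = substring(records$seq[i], starts, ends),
      length = ends - starts + 1L,
      parent = id,
      offset = starts,
      stringsAsFactors = FALSE
    )
  }
  chunks <- do.call(rbind, out)
  list(chunks = chunks,
       parent = stats::setNames(chunks$parent, chunks$id))
}
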