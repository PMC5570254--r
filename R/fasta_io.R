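#' Read a FASTA file of nucleotide sequences
#'
#' Reads assembled contigs or long reads from a FASTA file. The sequence ID is
#' the header token up to the first whitespace; the remainder of the header is
#' dropped. Residues are folded to uppercase and U is mapped to T, so both DNA
#' and RNA alphabets are accepted. IUPAC ambiguity codes are tolerated (they
#' are skipped later during k-mer counting).
#'
#' @param path Path to a FASTA-formatted file.
#' @return A data frame with columns `id`, `seq` and `length` (bp), one row
#'   per input record, in file order.
#' @details Duplicate IDs are an error, as downstream assignment tables key on
#'   the ID. A record in which more than half of the residues fall outside the
#'   IUPAC nucleotide alphabet is rejected with a hint that the file may
#'   contain protein sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence ID(s) in FASTA file: ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  # reject records that look like protein: > 50% residues outside IUPAC DNA
  iupac <- "ACGTNRYSWKMBDHV"
  nt <- nchar(gsub(sprintf("[^%s]", iupac), "", seqs))
  len <- nchar(seqs)
  bad <- which(len > 0L & (nt / len) < 0.5)
  if (length(bad) > 0L) {
    stop("record '", ids[bad[1]], "' has >50% non-nucleotide residues; ",
         "is this a protein FASTA file?")
  }
  if (any(len < 1L)) stop("record '", ids[which(len < 1L)[1]], "' is empty")
  data.frame(id = ids, seq = unname(seqs), length = len,
             stringsAsFactors = FALSE)
}

#' Write per-bin FASTA files and the assignments table
#'
#' Writes one FASTA file per distinct bin label (`bin_<label>.fasta`,
#' zero-padded) containing the member sequences with their original IDs and
#' residues, plus `assignments.tsv` summarising the ID, length, role, cluster
#' and bin of every input sequence. Sequences without a bin (discarded or
#' unbinned) go to `unbinned.fasta` when present.
#'
#' @param records Data frame from [read_fasta()] (columns `id`, `seq`,
#'   `length`).
#' @param bins Named vector/list mapping sequence ID to bin label; IDs absent
#'   from it are treated as unbinned.
#' @param out_dir Output directory (created if needed).
#' @param roles Optional named character vector of point roles per ID.
#' @param clusters Optional named vector of de novo cluster labels per ID
#'   (`-1` = noise).
#' @return Invisibly, the character vector of files written.
#' @export
write_bin_fastas <- function(records, bins, out_dir, roles = NULL,
                             clusters = NULL) {
  stopifnot(is.data.frame(records))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  bins <- unlist(bins)
  if (length(bins) > 0L && is.null(names(bins)))
    stop("'bins' must be named by sequence ID")
  missing_ids <- setdiff(names(bins), records$id)
  if (length(missing_ids) > 0L)
    stop("binned ID(s) not among records: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))

  bin_of <- bins[records$id]          # NA where unbinned
  labs <- sort(unique(as.character(stats::na.omit(bin_of))))
  width <- max(2L, nchar(labs))
  written <- character(0)
  for (lab in labs) {
    sel <- which(!is.na(bin_of) & as.character(bin_of) == lab)
    f <- file.path(out_dir, sprintf("bin_%0*s.fasta", width,
                                    gsub("\\s", "_", lab)))
    writeLines(as.vector(rbind(paste0(">", records$id[sel]),
                               records$seq[sel])), f)
    written <- c(written, f)
  }
  unb <- which(is.na(bin_of))
  if (length(unb) > 0L && length(labs) > 0L) {
    f <- file.path(out_dir, "unbinned.fasta")
    writeLines(as.vector(rbind(paste0(">", records$id[unb]),
                               records$seq[unb])), f)
    written <- c(written, f)
  }

  tab <- data.frame(
    sequence_id = records$id,
    length = records$length,
    role = if (is.null(roles)) NA_character_ else
      unname(roles[records$id]),
    cluster = if (is.null(clusters)) NA else unname(clusters[records$id]),
    bin = unname(bin_of),
    stringsAsFactors = FALSE
  )
  tsv <- file.path(out_dir, "assignments.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(c(written, tsv))
}

#' Read a custom per-sequence annotation table
#'
#' Parses a tab-separated file whose first column is a sequence ID and second
#' column a free-text annotation label, as used to overlay e.g. antibiotic
#' resistance gene tags on the 2D embedding.
#'
#' @param path Path to the TSV file.
#' @param known_ids Character vector of sequence IDs present in the dataset.
#' @return A list with `annotations` (named character vector ID -> label) and
#'   `unknown_ids` (IDs in the file but not in `known_ids`; reported, not
#'   fatal).
#' @export
read_annotations <- function(path, known_ids) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L)) {
    stop("annotation line ", which(ncols < 2L)[1],
         " has fewer than 2 tab-separated columns")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  ann <- vapply(parts, `[[`, character(1), 2L)
  unknown <- setdiff(ids, known_ids)
  if (length(unknown) > 0L) {
    warning(length(unknown), " annotation ID(s) not found among sequences: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  keep <- ids %in% known_ids
  list(annotations = stats::setNames(ann[keep], ids[keep]),
       unknown_ids = unknown)
}

#' Read a ground-truth table (sequence ID -> source genome)
#'
#' @param path Two-column TSV: `sequence_id`, `genome`. A header line is
#'   detected and skipped if its first field equals "sequence_id".
#' @return Named character vector mapping ID to genome label.
#' @export
read_ground_truth <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sequence_id", "genome"),
                           colClasses = "character")
  if (nrow(tab) > 0L && tab$sequence_id[1] == "sequence_id")
    tab <- tab[-1L, , drop = FALSE]
  stats::setNames(tab$genome, tab$sequence_id)
}

#' Write a FASTA file from a records data frame
#' @param records Data frame with `id` and `seq` columns.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  writeLines(as.vector(rbind(paste0(">", records$id), records$seq)), path)
  invisible(path)
}
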