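# End-to-end pipeline: read -> (chunk) -> roles -> signatures -> compress
# -> embed -> cluster -> decompress -> train/assign -> (aggregate) ->
# outputs. One master seed derives the stage seeds by fixed offsets so each
# stage is independently reproducible.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the binning pipeline with its
#' default. All defaults are deliberately conservative; the main knobs in
#' practice are the length thresholds (`t_b`, `t_c`), `min_pts` (decrease to
#' find small clusters) and `chunk_length` (enable to normalize cluster
#' density when contig lengths are very uneven).
#'
#' @param k Oligonucleotide length for signatures (pentamers by default).
#' @param transform Signature transform, `"clr"` or `"none"`.
#' @param t_b,t_c,min_len Length thresholds (bp) for point roles; see
#'   [assign_roles()].
#' @param chunk_length Chunk size in bp; 0 disables chunking.
#' @param compression Compression factor (0 = off; 1 = "1NN").
#' @param seed Master RNG seed.
#' @param perplexity,theta,max_iter t-SNE parameters; see [embed_2d()].
#' @param min_pts,eps DBSCAN parameters; see [dbscan_cluster()].
#' @param n_trees Random-forest size.
#' @return A list of class `bsb_config`.
#' @export
bsb_config <- function(k = 5, transform = "clr", t_b = 1000, t_c = 1000,
                       min_len = 500, chunk_length = 0, compression = 0,
                       seed = 1, perplexity = 30, theta = 0.5,
                       max_iter = 1000, min_pts = 20, eps = "auto",
                       n_trees = 500) {
  cfg <- list(k = k, transform = transform, t_b = t_b, t_c = t_c,
              min_len = min_len, chunk_length = chunk_length,
              compression = compression, seed = seed,
              perplexity = perplexity, theta = theta, max_iter = max_iter,
              min_pts = min_pts, eps = eps, n_trees = n_trees)
  class(cfg) <- "bsb_config"
  cfg
}

#' Bin a set of sequences (in memory)
#'
#' Runs the full bootstrapped supervised binning pipeline on a records data
#' frame and returns all intermediate and final assignments. See
#' [run_bin()] for the file-based front end.
#'
#' @param records Data frame from [read_fasta()] or
#'   [simulate_community()]`$records`.
#' @param config A [bsb_config()].
#' @return A list of class `bsb_binning` with elements `roles` (per working
#'   sequence), `compression`, `embedding`, `clusters`, `cluster_of`
#'   (decompressed cluster label per compressed point), `bin` (final bin per
#'   retained working sequence), `parent_bin` and `agreement` (chunked mode
#'   only), `chunk_map`, `records`, `work` (the working records: chunks in
#'   chunked mode), `config`, `log` (per-stage timings and counts).
#' @export
bin_sequences <- function(records, config = bsb_config()) {
  stopifnot(is.data.frame(records), inherits(config, "bsb_config"))
  log <- list()
  stamp <- function(stage, n_in, n_out, t0) {
    log[[stage]] <<- list(stage = stage, n_in = n_in, n_out = n_out,
                          seconds = round(as.numeric(Sys.time()) - t0, 3))
  }

  chunked <- config$chunk_length > 0
  chunk_map <- NULL
  work <- records
  if (chunked) {
    t0 <- as.numeric(Sys.time())
    chunk_map <- chunk_sequences(records, config$chunk_length,
                                 config$min_len)
    work <- chunk_map$chunks
    stamp("chunk", nrow(records), nrow(work), t0)
  }

  t0 <- as.numeric(Sys.time())
  roles <- assign_roles(work, config$t_b, config$t_c, config$min_len)
  retained <- names(roles)[roles != "discarded"]
  if (length(retained) == 0L)
    stop("no sequences retained: all are shorter than min_len (",
         config$min_len, " bp)")
  stamp("roles", nrow(work), length(retained), t0)

  t0 <- as.numeric(Sys.time())
  wr <- work[work$id %in% retained, , drop = FALSE]
  sig <- kmer_signatures(wr, k = config$k)
  features <- transform_signatures(sig, config$transform)
  stamp("signatures", length(retained), nrow(features), t0)

  bc <- names(roles)[roles %in% c("border", "cluster")]
  if (length(bc) < 4L)
    stop("too few border/cluster points to embed (", length(bc),
         "); decrease t_b/t_c")

  t0 <- as.numeric(Sys.time())
  cmap <- compress_points(features[bc, , drop = FALSE],
                          c = config$compression, seed = config$seed + 11L)
  stamp("compress", length(bc), length(cmap$representatives), t0)

  t0 <- as.numeric(Sys.time())
  emb <- embed_2d(features[cmap$representatives, , drop = FALSE],
                  perplexity = config$perplexity, seed = config$seed + 23L,
                  theta = config$theta, max_iter = config$max_iter)
  stamp("embed", length(cmap$representatives), nrow(emb$coords), t0)

  cl_reps <- cmap$representatives[roles[cmap$representatives] == "cluster"]
  if (length(cl_reps) < config$min_pts)
    stop("fewer cluster-point representatives (", length(cl_reps),
         ") than minPts (", config$min_pts, "); decrease minPts or t_c")
  t0 <- as.numeric(Sys.time())
  clusters <- dbscan_cluster(emb$coords[cl_reps, , drop = FALSE],
                             min_pts = config$min_pts, eps = config$eps)
  stamp("cluster", length(cl_reps), clusters$k, t0)

  # decompressed cluster labels: associates inherit their representative's
  # label; border reps/associates have no cluster label
  cluster_of <- decompress_labels(
    cmap, c(clusters$labels,
            stats::setNames(rep(NA_integer_,
                                sum(!cmap$representatives %in% cl_reps)),
                            setdiff(cmap$representatives, cl_reps))))

  t0 <- as.numeric(Sys.time())
  training <- build_training_set(clusters, cmap, features)
  lengths <- stats::setNames(work$length, work$id)
  result <- train_and_assign(training, features, roles, lengths,
                             min_len = config$min_len,
                             seed = config$seed + 37L,
                             n_trees = config$n_trees)
  stamp("classify", nrow(training$x), length(result$bin), t0)

  parent_bin <- NULL
  agreement <- NULL
  if (chunked) {
    t0 <- as.numeric(Sys.time())
    agg <- aggregate_chunk_bins(result$bin, chunk_map, lengths)
    parent_bin <- agg$bin
    agreement <- agg$agreement
    stamp("aggregate", length(result$bin), length(parent_bin), t0)
  }

  structure(list(roles = roles, compression = cmap, embedding = emb,
                 clusters = clusters, cluster_of = cluster_of,
                 bin = result$bin, k_bins = result$k_bins,
                 n_train = result$n_train, parent_bin = parent_bin,
                 agreement = agreement, chunk_map = chunk_map,
                 records = records, work = work, config = config,
                 log = log),
            class = "bsb_binning")
}

#' @export
print.bsb_binning <- function(x, ...) {
  cat("Bootstrapped supervised binning of", nrow(x$records), "sequences\n")
  if (!is.null(x$chunk_map))
    cat("  chunked mode:", nrow(x$work), "chunks of",
        x$config$chunk_length, "bp\n")
  cat("  roles:", paste(names(table(x$roles)), table(x$roles),
                        collapse = ", ", sep = "="), "\n")
  cat("  clusters:", x$clusters$k, " (minPts=", x$config$min_pts,
      ", eps=", signif(x$clusters$eps, 4), ")\n", sep = "")
  cat("  training rows:", x$n_train, "\n")
  cat("  bins:", x$k_bins, "over", length(x$bin), "sequences\n")
  invisible(x)
}

#' Bins at the level of the original input sequences
#'
#' In chunked mode the classifier labels chunks; this accessor returns the
#' majority-vote bin per original sequence. In unchunked mode it returns the
#' per-sequence bins directly.
#'
#' @param x A `bsb_binning`.
#' @return Named vector ID -> bin label.
#' @export
final_bins <- function(x) {
  stopifnot(inherits(x, "bsb_binning"))
  if (is.null(x$parent_bin)) x$bin else x$parent_bin
}

#' Run the binning pipeline on a FASTA file and write all outputs
#'
#' The file-based front end: reads the FASTA, runs [bin_sequences()], and
#' writes into `out_dir`: per-bin FASTA files and `assignments.tsv` (via
#' [write_bin_fastas()]), `coordinates.tsv` (embedded points),
#' `report.html` / `report.json`, `run_config.json` and `log.tsv` (stage,
#' n_in, n_out, seconds). In chunked mode bins are written at the level of
#' the original sequences and a `chunk_assignments.tsv` carries the
#' chunk-level detail.
#'
#' @param fasta Path to the input FASTA file.
#' @param out_dir Output directory (created).
#' @param config A [bsb_config()].
#' @param annotations Optional path to a custom annotation TSV (ID, label).
#' @return Invisibly, the `bsb_binning` object.
#' @export
run_bin <- function(fasta, out_dir, config = bsb_config(),
                    annotations = NULL) {
  records <- read_fasta(fasta)
  res <- bin_sequences(records, config)
  ann <- NULL
  if (!is.null(annotations))
    ann <- read_annotations(annotations, known_ids = records$id)$annotations
  write_outputs(res, out_dir, annotations = ann)
  invisible(res)
}

#' Write the output files of a binning run
#'
#' @param res A `bsb_binning`.
#' @param out_dir Output directory.
#' @param annotations Optional named vector ID -> annotation label.
#' @return Invisibly, `out_dir`.
#' @export
write_outputs <- function(res, out_dir, annotations = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chunked <- !is.null(res$chunk_map)

  # original-sequence-level assignments + per-bin FASTA
  bins <- final_bins(res)
  if (chunked) {
    roles_parent <- assign_roles(res$records, res$config$t_b,
                                 res$config$t_c, res$config$min_len)
    write_bin_fastas(res$records, bins, out_dir, roles = roles_parent)
    chunk_tab <- data.frame(
      sequence_id = res$work$id,
      length = res$work$length,
      parent = res$work$parent,
      role = unname(res$roles[res$work$id]),
      cluster = unname(res$cluster_of[res$work$id]),
      bin = unname(res$bin[res$work$id]),
      stringsAsFactors = FALSE)
    utils::write.table(chunk_tab,
                       file.path(out_dir, "chunk_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    write_bin_fastas(res$records, bins, out_dir, roles = res$roles,
                     clusters = res$cluster_of)
  }

  # embedded coordinates (representatives; associates at their rep's coords)
  coords <- res$embedding$coords
  assoc <- res$compression$assoc
  pts_ids <- c(rownames(coords), names(assoc))
  xy <- rbind(coords,
              coords[unname(assoc), , drop = FALSE])
  rownames(xy) <- pts_ids
  placed <- c(rep(FALSE, nrow(coords)), rep(TRUE, length(assoc)))
  coord_tab <- data.frame(sequence_id = pts_ids,
                          x = xy[, 1], y = xy[, 2],
                          role = unname(res$roles[pts_ids]),
                          placed_at_representative = placed,
                          stringsAsFactors = FALSE)
  utils::write.table(coord_tab, file.path(out_dir, "coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # report bundle
  pts <- data.frame(
    id = pts_ids, x = xy[, 1], y = xy[, 2],
    role = unname(res$roles[pts_ids]),
    cluster = unname(res$cluster_of[pts_ids]),
    bin = unname(res$bin[pts_ids]),
    annotation = if (is.null(annotations)) NA_character_ else
      unname(annotations[pts_ids]),
    placed_at_representative = placed,
    stringsAsFactors = FALSE)
  cl_counts <- table(res$cluster_of[!is.na(res$cluster_of) &
                                      res$cluster_of != -1])
  bin_counts <- table(res$bin)
  hulls <- convex_hulls(xy, res$cluster_of[!is.na(res$cluster_of)])
  render_report(list(points = pts, hulls = hulls,
                     counts = list(cluster = cl_counts, bin = bin_counts)),
                out_dir)

  cfg <- res$config
  cfg$eps_used <- res$clusters$eps
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_tab <- do.call(rbind, lapply(res$log, as.data.frame))
  utils::write.table(log_tab, file.path(out_dir, "log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
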