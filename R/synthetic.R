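# Synthetic metagenomic communities: Markov-chain genomes with
# genome-specific compositional signatures, assembly- or long-read-like
# fragment lengths, and an optional per-base error process. Every fragment
# carries a ground-truth genome label, so the whole pipeline is testable
# without external downloads.

BASES <- c("A", "C", "G", "T")

#' Simulate a genome with a distinct compositional signature
#'
#' Samples a per-context transition matrix from a symmetric Dirichlet
#' distribution and then a sequence from the resulting order-`order` Markov
#' chain. Different seeds give different transition matrices, hence genomes
#' with distinct oligonucleotide signatures -- the premise that makes
#' composition-based binning work. Lower `concentration` makes transition
#' rows more extreme and genomes more mutually distinct.
#'
#' @param length Genome length (bp); must be at least 4^(order + 1).
#' @param order Markov order (default 2: enough to create realistic pentamer
#'   structure, cheap to sample).
#' @param seed RNG seed; the genome is a deterministic function of it.
#' @param concentration Dirichlet concentration parameter (> 0).
#' @return A single DNA string.
#' @export
simulate_genome <- function(length, order = 2, seed = 1, concentration = 1) {
  stopifnot(length >= 4^(order + 1), order >= 0, concentration > 0)
  set.seed(seed)
  n_ctx <- 4L^order
  g <- matrix(stats::rgamma(n_ctx * 4L, shape = concentration),
              nrow = n_ctx)
  trans <- g / rowSums(g)
  cum <- t(apply(trans, 1L, cumsum))

  base <- integer(length)           # 0..3
  if (order > 0) base[seq_len(order)] <- sample.int(4L, order, replace = TRUE) - 1L
  ctx <- if (order > 0) sum(base[seq_len(order)] * 4L^((order - 1):0)) else 0L
  u <- stats::runif(length)
  for (t in (order + 1L):length) {
    p <- cum[ctx + 1L, ]
    b <- (u[t] > p[1L]) + (u[t] > p[2L]) + (u[t] > p[3L])
    base[t] <- b
    if (order > 0) ctx <- (ctx * 4L + b) %% n_ctx
  }
  paste(BASES[base + 1L], collapse = "")
}

#' Describe a synthetic community
#'
#' Bundles the simulation parameters. Two fragment-length presets are
#' provided: `"contigs"` emulates a short-read assembly (log-normal lengths,
#' meanlog = log 8000, sdlog = 0.8, no sequencing error) and `"nanopore"`
#' emulates raw long reads (meanlog = log 6000, sdlog = 1.0, per-base error
#' rate 0.1). Lengths are truncated to [min_frag, max_frag].
#'
#' @param n_genomes Number of source genomes.
#' @param genome_length Length of each genome (bp).
#' @param markov_order Markov order of the genome model.
#' @param concentration Dirichlet concentration (lower = more distinct
#'   genome signatures).
#' @param preset `"contigs"` or `"nanopore"`, or `NULL` to use the explicit
#'   length/error arguments.
#' @param meanlog,sdlog Log-normal fragment-length parameters.
#' @param min_frag,max_frag Truncation bounds (bp).
#' @param fragments_per_genome Fragments drawn per genome; a single count,
#'   or a vector of length `n_genomes` for uneven communities (e.g. one
#'   dominant organism).
#' @param error_rate Per-base probability of a sequencing error
#'   (substitution or single-base indel).
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 5, genome_length = 100000,
                           markov_order = 2, concentration = 1,
                           preset = c("contigs", "nanopore"),
                           meanlog = NULL, sdlog = NULL,
                           min_frag = 500, max_frag = 50000,
                           fragments_per_genome = 150, error_rate = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset)
    defaults <- switch(preset,
      contigs  = list(meanlog = log(8000), sdlog = 0.8, error_rate = 0),
      nanopore = list(meanlog = log(6000), sdlog = 1.0, error_rate = 0.1))
  } else {
    defaults <- list(meanlog = log(8000), sdlog = 0.8, error_rate = 0)
  }
  spec <- list(n_genomes = n_genomes, genome_length = genome_length,
               markov_order = markov_order, concentration = concentration,
               meanlog = if (is.null(meanlog)) defaults$meanlog else meanlog,
               sdlog = if (is.null(sdlog)) defaults$sdlog else sdlog,
               min_frag = min_frag,
               max_frag = min(max_frag, genome_length),
               fragments_per_genome =
                 rep_len(fragments_per_genome, n_genomes),
               error_rate = if (is.null(error_rate)) defaults$error_rate
                            else error_rate)
  class(spec) <- "community_spec"
  spec
}

# Truncated log-normal fragment lengths (resample until inside the bounds).
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Apply a per-base error process to a sequence
#'
#' At each position, independently with probability `error_rate`, one error
#' occurs: a substitution to a different base (probability 1/2 given an
#' error), a single-base insertion after the position (1/4), or a deletion
#' of the position (1/4) -- a crude stand-in for nanopore-style noise.
#'
#' @param seq DNA string.
#' @param error_rate Per-base error probability.
#' @return The corrupted DNA string.
#' @export
corrupt_sequence <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  err <- which(stats::runif(n) < error_rate)
  if (length(err) == 0L) return(seq)
  type <- sample(c("sub", "ins", "del"), length(err), replace = TRUE,
                 prob = c(0.5, 0.25, 0.25))
  out <- chars
  subs <- err[type == "sub"]
  if (length(subs) > 0L) {
    shift <- sample.int(3L, length(subs), replace = TRUE)
    out[subs] <- BASES[((match(chars[subs], BASES) - 1L + shift) %% 4L) + 1L]
  }
  ins <- err[type == "ins"]
  if (length(ins) > 0L) {
    out[ins] <- paste0(out[ins], sample(BASES, length(ins), replace = TRUE))
  }
  out[err[type == "del"]] <- ""
  paste(out, collapse = "")
}

#' Simulate a metagenomic community with ground truth
#'
#' Generates `n_genomes` Markov-chain genomes, draws fragments with
#' uniformly random start positions and truncated log-normal lengths, and
#' applies the error process. Fragment IDs encode the genome and fragment
#' index (`g<g>_f<i>`); the ground-truth table maps every fragment to its
#' source genome. Output is byte-identical for a fixed seed.
#'
#' @param spec A `community_spec`.
#' @param seed Master RNG seed.
#' @return A list with `records` (data frame `id`, `seq`, `length`),
#'   `truth` (named vector ID -> genome label), `genomes` (named vector of
#'   genome sequences) and `spec`.
#' @export
simulate_community <- function(spec = community_spec(), seed = 1) {
  stopifnot(inherits(spec, "community_spec"))
  genomes <- vapply(seq_len(spec$n_genomes), function(g) {
    simulate_genome(spec$genome_length, spec$markov_order,
                    seed = seed + 1000L * g,
                    concentration = spec$concentration)
  }, character(1))
  names(genomes) <- paste0("genome", seq_len(spec$n_genomes))

  set.seed(seed)
  recs <- vector("list", spec$n_genomes)
  for (g in seq_len(spec$n_genomes)) {
    m <- spec$fragments_per_genome[g]
    lens <- rlnorm_trunc(m, spec$meanlog, spec$sdlog,
                         spec$min_frag, spec$max_frag)
    starts <- vapply(lens, function(l)
      sample.int(spec$genome_length - l + 1L, 1L), integer(1))
    frags <- substring(genomes[g], starts, starts + lens - 1L)
    if (spec$error_rate > 0) {
      frags <- vapply(frags, corrupt_sequence, character(1),
                      error_rate = spec$error_rate, USE.NAMES = FALSE)
    }
    recs[[g]] <- data.frame(id = sprintf("g%d_f%d", g, seq_len(m)),
                            seq = frags, length = nchar(frags),
                            stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  truth <- stats::setNames(
    rep(names(genomes), times = spec$fragments_per_genome), records$id)
  list(records = records, truth = truth, genomes = genomes, spec = spec)
}
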