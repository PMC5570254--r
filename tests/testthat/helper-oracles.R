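# Independent oracles and shared fixtures. The oracles are deliberately
# naive (dictionary counting, O(n^2) closures) and never share code with
# the implementation they check.

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# naive canonical k-mer frequency vector via a dictionary of window counts
oracle_signature <- function(seq, k) {
  all_k <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE),
                      1L, paste, collapse = ""))
  rc_all <- vapply(all_k, revcomp_str, character(1))
  feats <- sort(unique(ifelse(all_k <= rc_all, all_k, rc_all)))
  starts <- seq_len(nchar(seq) - k + 1L)
  wins <- substring(seq, starts, starts + k - 1L)
  wins <- wins[!grepl("[^ACGT]", wins)]
  canon <- ifelse(wins <= rc_all[wins], wins, rc_all[wins])
  counts <- table(factor(canon, levels = feats))
  out <- stats::setNames(as.numeric(counts), feats)
  if (length(wins) > 0L) out <- out / length(wins)
  out
}

random_dna <- function(n, p = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# brute-force DBSCAN by transitive closure of density-reachability
oracle_dbscan <- function(coords, min_pts, eps) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  within <- d <= eps
  core <- rowSums(within) >= min_pts
  labels <- rep(-1L, n)
  k <- 0L
  # connected components over core points (edges: core pairs within eps)
  comp <- rep(NA_integer_, n)
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      nb <- which(within[v, ] & core & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  labels[core] <- comp[core]
  # border points join a component of some core neighbour
  for (i in which(!core)) {
    cn <- which(within[i, ] & core)
    if (length(cn) > 0L) labels[i] <- comp[cn[1L]]
  }
  labels
}

# do two labelings agree up to renumbering of non-noise labels, allowing
# DBSCAN border-point ambiguity (a non-core point adjacent to cores of
# several clusters may legally join any of them)?
same_clustering <- function(a, b, coords, min_pts, eps) {
  stopifnot(length(a) == length(b))
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  d <- as.matrix(stats::dist(coords))
  within <- d <= eps
  core <- rowSums(within) >= min_pts
  # the partition restricted to core points must match exactly
  ca <- a[core]; cb <- b[core]
  if (length(unique(ca)) != length(unique(cb))) return(FALSE)
  if (any(ca == -1L) || any(cb == -1L)) return(FALSE)
  map <- tapply(cb, ca, function(x) length(unique(x)))
  if (any(map != 1L)) return(FALSE)
  # each assigned border point must sit in a cluster owning a core neighbour
  for (i in which(!core & a != -1L)) {
    cn <- which(within[i, ] & core)
    if (!(a[i] %in% a[cn]) || !(b[i] %in% b[cn])) return(FALSE)
  }
  TRUE
}

# trustworthiness of an embedding: penalizes points entering a 2D
# neighbourhood that were not neighbours in the original space
oracle_trustworthiness <- function(X, Y, k = 10) {
  n <- nrow(X)
  rank_x <- t(apply(as.matrix(stats::dist(X)), 1L, rank,
                    ties.method = "first"))
  d_y <- as.matrix(stats::dist(Y))
  total <- 0
  for (i in seq_len(n)) {
    nn_y <- order(d_y[i, ])[2:(k + 1L)]
    r <- rank_x[i, nn_y] - 1L   # rank among others (self has rank 1)
    total <- total + sum(pmax(r - k, 0))
  }
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * total
}

# -- cached fixtures (built once per test run) -----------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default 5-genome community used across pipeline-level tests
default_sim <- function() {
  cached("default_sim",
         bootbin::simulate_community(bootbin::community_spec(), seed = 42))
}

default_run <- function() {
  cached("default_run", {
    sim <- default_sim()
    bootbin::bin_sequences(sim$records, bootbin::bsb_config(seed = 7))
  })
}

seq_lengths <- function(records) {
  stats::setNames(records$length, records$id)
}

# three well-separated Gaussian clouds in signature-like dimension
three_clouds <- function(n_per = 40, dim = 512, sep = 12, seed = 99) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(3 * dim), nrow = 3) * sep / sqrt(dim)
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(stats::rnorm(n_per * dim, sd = 0.5), ncol = dim), 2,
          centers[i, ], `+`)
  }))
  rownames(x) <- paste0("p", seq_len(3 * n_per))
  list(x = x, label = rep(1:3, each = n_per))
}
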