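test_that("genome simulation is deterministic per seed", {
  g1 <- simulate_genome(5000, order = 2, seed = 9)
  g2 <- simulate_genome(5000, order = 2, seed = 9)
  expect_identical(g1, g2)
  expect_false(identical(g1, simulate_genome(5000, order = 2, seed = 10)))
  expect_equal(nchar(g1), 5000L)
  expect_false(grepl("[^ACGT]", g1))
})

test_that("order-0 symmetric genomes have near-uniform base frequencies", {
  # with a high Dirichlet concentration the base distribution is close to
  # uniform; each count should fall within 3 sigma of the binomial mean
  n <- 10000
  g <- simulate_genome(n, order = 0, seed = 4, concentration = 200)
  counts <- table(strsplit(g, "")[[1]])
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n * 0.25) < 3.5 * sigma + n * 0.05))
})

test_that("different seeds give more distinct signatures than two windows
           of one genome", {
  gA <- simulate_genome(100000, seed = 1)
  gB <- simulate_genome(100000, seed = 2)
  winA1 <- substr(gA, 1, 50000)
  winA2 <- substr(gA, 50001, 100000)
  sig <- transform_signatures(kmer_signatures(
    c(A1 = winA1, A2 = winA2, B = substr(gB, 1, 50000)), k = 5))
  d <- as.matrix(dist(sig))
  expect_gt(d["A1", "B"], d["A1", "A2"])
  expect_gt(d["A2", "B"], d["A1", "A2"])
})

test_that("error-free fragments are exact substrings of their genome", {
  spec <- community_spec(n_genomes = 2, genome_length = 30000,
                         fragments_per_genome = 10)
  sim <- simulate_community(spec, seed = 5)
  expect_equal(nrow(sim$records), 20L)
  expect_length(sim$truth, 20L)
  for (i in seq_len(nrow(sim$records))) {
    g <- sim$genomes[[sim$truth[sim$records$id[i]]]]
    expect_true(grepl(sim$records$seq[i], g, fixed = TRUE))
  }
})

test_that("the error process produces the expected edit distance", {
  set.seed(33)
  g <- simulate_genome(6000, seed = 3)
  frag <- substr(g, 1, 5000)
  rate <- 0.02
  noisy <- corrupt_sequence(frag, rate)
  edits <- utils::adist(frag, noisy)[1, 1]
  mu <- 5000 * rate
  sigma <- sqrt(5000 * rate * (1 - rate))
  expect_lt(abs(edits - mu), 3 * sigma)
  expect_identical(corrupt_sequence(frag, 0), frag)
})

test_that("community output is byte-identical for a fixed seed", {
  spec <- community_spec(n_genomes = 2, genome_length = 20000,
                         fragments_per_genome = 5, preset = "nanopore")
  s1 <- simulate_community(spec, seed = 8)
  s2 <- simulate_community(spec, seed = 8)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
})

test_that("lower Dirichlet concentration spreads genome signatures apart", {
  mean_dist <- function(conc, seed) {
    sig <- transform_signatures(kmer_signatures(
      vapply(1:3, function(g)
        simulate_genome(20000, seed = seed + g, concentration = conc),
        character(1)), k = 5))
    mean(dist(sig))
  }
  lows <- vapply(1:4, function(s) mean_dist(0.2, 100 * s), numeric(1))
  highs <- vapply(1:4, function(s) mean_dist(5, 100 * s), numeric(1))
  # paired, one-sided rank comparison over seeds
  expect_true(all(lows > highs))
})

test_that("the default community is linearly separable in signature space", {
  sim <- default_sim()
  sig <- transform_signatures(kmer_signatures(sim$records, k = 5))
  set.seed(10)
  train <- sort(sample(nrow(sig), nrow(sig) %/% 2))
  test <- setdiff(seq_len(nrow(sig)), train)
  labs <- sim$truth[rownames(sig)]
  centroids <- do.call(rbind, lapply(split(train, labs[train]), function(ix)
    colMeans(sig[ix, , drop = FALSE])))
  d <- as.matrix(dist(rbind(centroids, sig[test, ])))
  d <- d[-(1:nrow(centroids)), 1:nrow(centroids), drop = FALSE]
  pred <- rownames(centroids)[max.col(-d)]
  expect_gte(mean(pred == labs[test]), 0.95)
})
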