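mk_clusters <- function(labels) {
  structure(list(labels = labels, k = length(unique(labels[labels != -1L])),
                 min_pts = 2, eps = 1), class = "cluster_labels")
}

mk_cmap <- function(reps, assoc = setNames(character(0), character(0)),
                    c = 1L) {
  structure(list(representatives = reps, assoc = assoc, c = c, seed = 1),
            class = "compression_map")
}

test_that("noise points are excluded from the training set", {
  n <- 100
  ids <- paste0("p", seq_len(n))
  feats <- matrix(rnorm(n * 4), nrow = n, dimnames = list(ids, NULL))
  labels <- setNames(c(rep(1L, 45), rep(2L, 45), rep(-1L, 10)), ids)
  tr <- build_training_set(mk_clusters(labels), mk_cmap(ids, c = 0L), feats)
  expect_equal(nrow(tr$x), 90L)
  expect_false(any(is.na(tr$y)))
  expect_equal(nlevels(tr$y), 2L)
})

test_that("decompression doubles the training set under c = 1", {
  reps <- paste0("r", 1:50)
  assoc <- setNames(reps, paste0("a", 1:50))
  ids <- c(reps, names(assoc))
  feats <- matrix(rnorm(100 * 4), nrow = 100, dimnames = list(ids, NULL))
  labels <- setNames(rep(c(1L, 2L), 25), reps)
  tr <- build_training_set(mk_clusters(labels), mk_cmap(reps, assoc), feats)
  expect_equal(nrow(tr$x), 100L)
  # associates inherit their representative's label
  expect_equal(unname(tr$y[match(names(assoc), rownames(tr$x))]),
               unname(tr$y[match(reps, rownames(tr$x))]))
})

test_that("all-noise clustering is a hard error", {
  ids <- paste0("p", 1:10)
  feats <- matrix(rnorm(40), nrow = 10, dimnames = list(ids, NULL))
  labels <- setNames(rep(-1L, 10), ids)
  expect_error(
    build_training_set(mk_clusters(labels), mk_cmap(ids, c = 0L), feats),
    "no clusters to learn from")
})

test_that("a single cluster assigns everything to one bin with a warning", {
  ids <- paste0("p", 1:30)
  feats <- matrix(rnorm(30 * 4), nrow = 30, dimnames = list(ids, NULL))
  roles <- setNames(rep("cluster", 30), ids)
  lengths <- setNames(rep(2000, 30), ids)
  tr <- list(x = feats[1:20, ], y = factor(rep(1L, 20)))
  expect_warning(res <- train_and_assign(tr, feats, roles, lengths),
                 "one cluster")
  expect_equal(unname(unique(res$bin)), 1L)
  expect_length(res$bin, 30L)
})

test_that("re-predicted cluster points keep their own cluster's label", {
  res <- default_run()
  cl <- res$cluster_of
  cl <- cl[!is.na(cl) & cl != -1L]
  agree <- mean(res$bin[names(cl)] == cl)
  expect_gte(agree, 0.95)
})

test_that("bins partition the retained sequences and cannot invent classes", {
  res <- default_run()
  retained <- names(res$roles)[res$roles != "discarded"]
  expect_setequal(names(res$bin), retained)
  expect_true(all(res$bin %in% res$clusters$labels))
})

test_that("chunk bins aggregate to parents by bp-majority with tie rules", {
  cm <- list(parent = c("p|chunk1" = "p", "p|chunk2" = "p",
                        "p|chunk3" = "p"))
  lens <- c("p|chunk1" = 3000, "p|chunk2" = 3000, "p|chunk3" = 1000)
  bins <- c("p|chunk1" = 1L, "p|chunk2" = 1L, "p|chunk3" = 2L)
  agg <- aggregate_chunk_bins(bins, cm, lens)
  expect_equal(unname(agg$bin["p"]), 1L)
  expect_equal(unname(agg$agreement["p"]), 6000 / 7000)

  # single chunk: its own bin, full agreement
  agg1 <- aggregate_chunk_bins(c("q|chunk1" = 5L),
                               list(parent = c("q|chunk1" = "q")),
                               c("q|chunk1" = 1200))
  expect_equal(unname(agg1$bin["q"]), 5L)
  expect_equal(unname(agg1$agreement["q"]), 1)

  # exact bp tie between bins 3 and 7 resolves to the smaller label
  cm2 <- list(parent = c("r|chunk1" = "r", "r|chunk2" = "r"))
  agg2 <- aggregate_chunk_bins(c("r|chunk1" = 7L, "r|chunk2" = 3L), cm2,
                               c("r|chunk1" = 3000, "r|chunk2" = 3000))
  expect_equal(unname(agg2$bin["r"]), 3L)

  # a parent with zero binned chunks is absent (unbinned)
  agg3 <- aggregate_chunk_bins(c("p|chunk1" = 1L),
                               list(parent = c("p|chunk1" = "p",
                                               "s|chunk1" = "s")),
                               c("p|chunk1" = 3000, "s|chunk1" = 400))
  expect_false("s" %in% names(agg3$bin))
})
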