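rand_features <- function(n, d = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), nrow = n)
  rownames(m) <- paste0("p", seq_len(n))
  m
}

test_that("c = 0 keeps every point as a representative", {
  x <- rand_features(10)
  cm <- compress_points(x, c = 0, seed = 3)
  expect_equal(cm$representatives, rownames(x))
  expect_length(cm$assoc, 0L)
})

test_that("c = 1 on 10 points yields 5 representatives, 5 associates", {
  x <- rand_features(10)
  cm <- compress_points(x, c = 1, seed = 3)
  expect_length(cm$representatives, 5L)
  expect_length(cm$assoc, 5L)
})

test_that("greedy grouping exhausts the pool (c = 2, n = 10 gives 4 reps)", {
  # 10 points absorbed in groups of (1 rep + 2 assoc) leaves a final
  # representative with a single associate: 4 reps, simulated greedily
  x <- rand_features(10)
  cm <- compress_points(x, c = 2, seed = 3)
  expect_length(cm$representatives, 4L)
  expect_length(cm$assoc, 6L)
})

test_that("associates map to their nearest unassigned neighbour structure", {
  # two tight pairs far apart: each representative must absorb its own twin
  x <- rbind(p1 = c(0, 0), p2 = c(0.1, 0), p3 = c(100, 0), p4 = c(100.1, 0))
  cm <- compress_points(x, c = 1, seed = 5)
  pair <- c(p1 = "p2", p2 = "p1", p3 = "p4", p4 = "p3")
  for (a in names(cm$assoc)) {
    expect_equal(unname(cm$assoc[a]), unname(pair[a]))
  }
})

test_that("representatives and associates partition the point set", {
  for (n in c(1, 10, 101, 1000)) {
    for (cc in c(0, 1, 2, 5)) {
      x <- rand_features(n, seed = n + cc)
      cm <- compress_points(x, c = cc, seed = 11)
      expect_length(intersect(cm$representatives, names(cm$assoc)), 0L)
      expect_setequal(c(cm$representatives, names(cm$assoc)), rownames(x))
      r <- length(cm$representatives)
      expect_gte(r, ceiling(n / (cc + 1)))
      expect_lte(r, ceiling(n / (cc + 1)) + cc)
    }
  }
})

test_that("a fixed seed reproduces the compression map exactly", {
  x <- rand_features(200)
  cm1 <- compress_points(x, c = 3, seed = 42)
  cm2 <- compress_points(x, c = 3, seed = 42)
  expect_identical(cm1, cm2)
  cm3 <- compress_points(x, c = 3, seed = 43)
  expect_false(identical(cm1$representatives, cm3$representatives))
})

test_that("decompression propagates representative labels to associates", {
  cm <- structure(list(representatives = c("r1", "r2"),
                       assoc = c(a1 = "r1"), c = 1L, seed = 1),
                  class = "compression_map")
  out <- decompress_labels(cm, c(r1 = "A", r2 = "B"))
  expect_equal(out, c(r1 = "A", r2 = "B", a1 = "A"))
  expect_error(decompress_labels(cm, c(r1 = "A")), "r2")

  # empty assoc: decompression is the identity on the representatives
  cm0 <- compress_points(rand_features(7), c = 0, seed = 1)
  labs <- setNames(sample(1:2, 7, replace = TRUE), cm0$representatives)
  expect_equal(decompress_labels(cm0, labs), labs)
})

test_that("decompression covers exactly the compressed point set", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:300, 1)
    x <- rand_features(n, seed = i)
    cm <- compress_points(x, c = sample(0:4, 1), seed = i)
    labs <- setNames(sample(1:3, length(cm$representatives), replace = TRUE),
                     cm$representatives)
    out <- decompress_labels(cm, labs)
    expect_length(out, length(cm$representatives) + length(cm$assoc))
    expect_setequal(names(out), rownames(x))
  }
})
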