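write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("read_fasta parses records, folds case, and drops descriptions", {
  f <- write_tmp_fasta(c(">s1", "ACGT"))
  rec <- read_fasta(f)
  expect_equal(rec$id, "s1")
  expect_equal(rec$seq, "ACGT")
  expect_equal(rec$length, 4L)

  f <- write_tmp_fasta(c(">s1 some description", "ac", "gu"))
  rec <- read_fasta(f)
  expect_equal(rec$id, "s1")
  expect_equal(rec$seq, "ACGT")   # multi-line folded, lowercase up, U -> T
})

test_that("read_fasta rejects bad input", {
  expect_error(read_fasta(write_tmp_fasta(character(0))), "no sequences")
  expect_error(read_fasta(write_tmp_fasta(c(">s1", "ACGT", ">s1", "GGGG"))),
               "s1")
  expect_error(
    read_fasta(write_tmp_fasta(c(">p1", "MKLVINLIFEQPQPELEL"))),
    "protein")
})

test_that("per-bin FASTA output partitions the binned sequences", {
  rec <- data.frame(id = c("s1", "s2", "s3"),
                    seq = c("ACGTAA", "CCCGGG", "TTTTAA"),
                    length = c(6L, 6L, 6L), stringsAsFactors = FALSE)
  out <- tempfile()
  files <- write_bin_fastas(rec, c(s1 = 1, s2 = 1, s3 = 2), out)
  fastas <- grep("bin_.*\\.fasta$", files, value = TRUE)
  expect_length(fastas, 2L)
  b1 <- read_fasta(fastas[1])
  expect_equal(nrow(b1), 2L)

  # round trip: concatenation of all bin files reproduces the binned set
  all_back <- do.call(rbind, lapply(fastas, read_fasta))
  expect_setequal(paste(all_back$id, all_back$seq),
                  paste(rec$id, rec$seq))

  tab <- read.table(file.path(out, "assignments.tsv"), sep = "\t",
                    header = TRUE)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(!is.na(tab$bin)), 3L)
})

test_that("empty bin mapping writes only the summary table", {
  rec <- data.frame(id = "s1", seq = "ACGT", length = 4L,
                    stringsAsFactors = FALSE)
  out <- tempfile()
  files <- write_bin_fastas(rec, setNames(integer(0), character(0)), out)
  expect_length(grep("\\.fasta$", files), 0L)
  expect_true(file.exists(file.path(out, "assignments.tsv")))
})

test_that("binned IDs must exist among the records", {
  rec <- data.frame(id = "s1", seq = "ACGT", length = 4L,
                    stringsAsFactors = FALSE)
  expect_error(write_bin_fastas(rec, c(sX = 1), tempfile()), "sX")
})

test_that("annotation tables are parsed with unknown-ID reporting", {
  f <- tempfile()
  writeLines("s1\tvanB", f)
  ann <- read_annotations(f, known_ids = "s1")
  expect_equal(ann$annotations, c(s1 = "vanB"))
  expect_length(ann$unknown_ids, 0L)

  writeLines("sX\thighCov", f)
  expect_warning(ann <- read_annotations(f, known_ids = "s1"), "sX")
  expect_equal(ann$unknown_ids, "sX")
  expect_length(ann$annotations, 0L)

  writeLines("s1", f)
  expect_error(read_annotations(f, known_ids = "s1"), "line 1")
})

test_that("fasta write/read round trip preserves the (id, seq) multiset", {
  set.seed(3)
  rec <- data.frame(id = paste0("r", 1:20),
                    seq = replicate(20, random_dna(sample(10:200, 1))),
                    stringsAsFactors = FALSE)
  rec$length <- nchar(rec$seq)
  f <- tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  back <- read_fasta(f)
  expect_identical(back$id, rec$id)
  expect_identical(back$seq, rec$seq)
})
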