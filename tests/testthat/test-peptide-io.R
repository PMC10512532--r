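test_that("FASTA parsing preserves records, order and round-trips", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">p1", "ACDE", ">p2", "GGGG"), f)
  ds <- read_fasta(f)
  expect_s3_class(ds, "peptide_set")
  expect_equal(ds$id, c("p1", "p2"))
  expect_equal(nchar(ds$sequence), c(4L, 4L))

  out <- tempfile(fileext = ".fasta")
  write_fasta(ds, out)
  expect_equal(read_fasta(out)[, c("id", "sequence")],
               ds[, c("id", "sequence")])

  # duplicate bodies under distinct ids are both kept at parse time
  writeLines(c(">a", "ACDE", ">b", "ACDE"), f)
  expect_equal(nrow(read_fasta(f)), 2L)
})

test_that("validation rejects or drops non-standard residues", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACBZ"), f)
  expect_error(read_fasta(f), "B,Z")
  writeLines(c(">x", "ACBZ", ">y", "acde"), f)
  expect_warning(ds <- read_fasta(f, mode = "lenient"), "invalid")
  expect_equal(ds$sequence, "ACDE")   # case-normalised, invalid dropped
  expect_error(peptide_set("e", ""), "non-empty|empty")
  expect_error(peptide_set(c("a", "a"), c("AC", "CA")), "duplicate")
})

test_that("TSV reader honours id/sequence/label columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tsequence\tlabel", "p1\tACDE\tpositive",
               "p2\tGGGG\tnegative"), f)
  ds <- read_peptide_tsv(f)
  expect_equal(as.character(ds$label), c("positive", "negative"))
})

test_that("deduplication keeps first occurrences and removes label conflicts", {
  ds <- peptide_set(c("a", "b", "c"), c("ACDE", "ACDE", "GGGG"),
                    label = c("positive", "positive", "negative"))
  dd <- deduplicate(ds)
  expect_equal(dd$id, c("a", "c"))

  conflicted <- peptide_set(c("a", "b"), c("ACDE", "ACDE"),
                            label = c("positive", "negative"))
  expect_warning(dd2 <- deduplicate(conflicted), "conflict")
  expect_equal(nrow(dd2), 0L)

  unique_ds <- peptide_set(c("a", "b"), c("ACDE", "GGGG"))
  expect_equal(deduplicate(unique_ds)$id, unique_ds$id)
})

test_that("stratified split reproduces per-class rounding and partitions exactly", {
  ds <- peptide_set(paste0("p", 1:420),
                    vapply(1:420, function(i) random_peptide(8), ""),
                    label = rep(c("positive", "negative"), c(133, 287)))
  sp <- split_dataset(ds, 0.8, seed = 11)
  expect_equal(sum(sp$train$label == "positive"), 106L)
  expect_equal(sum(sp$train$label == "negative"), 230L)

  # determinism and exact partition
  sp2 <- split_dataset(ds, 0.8, seed = 11)
  expect_identical(sp$train$id, sp2$train$id)
  expect_setequal(c(sp$train$id, sp$test$id), ds$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)

  tiny <- peptide_set(c("a", "b", "c"), c("AC", "CA", "GG"),
                      label = c("positive", "positive", "negative"))
  expect_error(split_dataset(tiny, 0.9), "empty")
})
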