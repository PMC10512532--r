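test_that("generated peptides are valid, labelled and reproducible", {
  ds <- synth_peptides(30, 40, length_range = c(5, 25), s = 1, seed = 3)
  expect_s3_class(ds, "peptide_set")     # construction implies validation
  expect_equal(sum(ds$label == "positive"), 30L)
  expect_equal(sum(ds$label == "negative"), 40L)
  expect_true(all(nchar(ds$sequence) >= 5 & nchar(ds$sequence) <= 25))
  expect_identical(ds, synth_peptides(30, 40, length_range = c(5, 25),
                                      s = 1, seed = 3))
  expect_error(synth_peptides(10, 10, length_range = c(1, 5)))
})

test_that("zero signal strength makes the classes indistinguishable", {
  ds <- synth_peptides(100, 100, s = 0, seed = 19)
  X <- encode_features(ds, "AAC")
  m <- tune_and_fit("LR", X, ds$label, k = 5, seed = 1)
  expect_lte(abs(m$cv_mcc), 0.2)
})

test_that("class separability grows with the signal strength", {
  mcc_at <- function(s, seed) {
    ds <- synth_peptides(75, 75, s = s, seed = seed)
    tune_and_fit("LR", encode_features(ds, "AAC"), ds$label,
                 k = 5, seed = 1)$cv_mcc
  }
  med <- vapply(c(0, 0.5, 1), function(s)
    median(vapply(1:3, function(sd) mcc_at(s, 100 + sd), numeric(1))),
    numeric(1))
  expect_false(is.unsorted(med))
  expect_gte(med[3], 0.6)
})

test_that("planted PFV columns carry exactly the requested signal", {
  sp0 <- synth_planted_pfv(200, 30, 5, shift = 0, seed = 7)
  aucs0 <- apply(sp0$X[, sp0$informative], 2,
                 function(cf) auc_midrank(sp0$y, cf))
  expect_true(all(aucs0 > 0.4 & aucs0 < 0.6))

  sp <- synth_planted_pfv(200, 30, 5, shift = 0.3, seed = 7)
  aucs <- apply(sp$X[, sp$informative], 2,
                function(cf) auc_midrank(sp$y, cf))
  expect_true(all(aucs >= 0.75))
  noise <- setdiff(seq_len(30), sp$informative)
  aucs_n <- apply(sp$X[, noise], 2, function(cf) auc_midrank(sp$y, cf))
  expect_true(all(abs(aucs_n - 0.5) < 0.15))
  expect_true(all(sp$X >= 0 & sp$X <= 1))
})
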