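test_that("architecture cardinality is the encoder-algorithm cross-product", {
  arch <- stack_architecture()
  expect_equal(nrow(arch$specs), 130L)
  expect_equal(nrow(arch$specs),
               length(arch$encoders) * length(arch$algorithms))
  expect_true("MLP-PAAC" %in% arch$specs$column)
  small <- stack_architecture(c("AAC", "PCP"), c("LR", "NB", "KNN"))
  expect_equal(small$specs$column[1:3],
               c("LR-AAC", "NB-AAC", "KNN-AAC"))
  expect_error(stack_architecture(c("AAC", "AAC")))
})

test_that("out-of-fold PFV is bounded, complete and reproducible", {
  ds <- tiny_labeled_set(20, 20, seed = 5)
  arch <- stack_architecture(c("AAC", "PCP"), c("LR", "NB"))
  pfv <- build_training_pfv(arch, ds, k = 4, seed = 9, tune_k = 3)
  expect_equal(dim(pfv), c(40L, 4L))
  expect_true(all(pfv >= 0 & pfv <= 1))
  expect_false(anyNA(pfv))
  expect_equal(attr(pfv, "provenance"), "out_of_fold")
  pfv2 <- build_training_pfv(arch, ds, k = 4, seed = 9, tune_k = 3)
  expect_identical(pfv, pfv2)
})

test_that("external PFV aligns columns with the training PFV", {
  ds <- tiny_labeled_set(15, 15, seed = 6)
  arch <- stack_architecture(c("AAC", "PCP"), c("LR", "KNN"))
  baselines <- fit_full_baselines(arch, ds, tune_k = 3, seed = 1)
  one <- peptide_set("q1", "ACDKWYRF")
  pfv <- build_external_pfv(arch, baselines, one)
  expect_equal(dim(pfv), c(1L, 4L))
  expect_equal(colnames(pfv), arch$specs$column)
  expect_equal(attr(pfv, "provenance"), "full_model")
})

test_that("meta-model on a perfectly informative PF separates the classes", {
  set.seed(2)
  y <- rep(c(1, 0), each = 30)
  pfv <- cbind(perfect = y, noise = runif(60))
  meta <- fit_meta(pfv, y, mask = c(TRUE, FALSE), ncomp = 1)
  pred <- predict(meta, pfv)
  expect_equal(score(y, pred$confidence)$MCC, 1)
  # boundary rule: confidence exactly at threshold is positive
  expect_equal(predict(meta, pfv)$class[1], "positive")
  # missing selected columns are an error
  colnames(pfv) <- c("a", "b")
  expect_error(fit_meta(pfv, y, mask = c(FALSE, FALSE)), "mask")
})

test_that("meta predictions are robust and order-invariant", {
  set.seed(11)
  y <- rep(c(1, 0), each = 25)
  pfv <- matrix(runif(50 * 6), 50, dimnames = list(NULL, paste0("c", 1:6)))
  pfv[, 1] <- pmin(pmax(pfv[, 1] + 0.4 * (2 * y - 1), 0), 1)
  meta <- fit_meta(pfv, y, k = 5, seed = 1)
  # all-zero row scores without crashing, inside [0,1]
  z <- predict(meta, matrix(0, 1, 6, dimnames = list("z", paste0("c", 1:6))))
  expect_gte(z$confidence, 0); expect_lte(z$confidence, 1)
  # permuting sample order permutes predictions identically
  ord <- sample(50)
  p1 <- predict(meta, pfv)$confidence
  p2 <- predict(meta, pfv[ord, ])$confidence
  expect_equal(p2, p1[ord])
})
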