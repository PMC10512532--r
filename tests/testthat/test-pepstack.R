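# end-to-end fit on a small reduced architecture (kept deliberately
# light; the full-size study conditions run in test-acceptance.R)
fit_small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- synth_peptides(40, 40, length_range = c(8, 20), s = 1, seed = 2)
      cache <<- pepstack(ds, encoders = c("AAC", "PCP"),
                         algorithms = c("LR", "NB", "KNN"),
                         k = 5, tune_k = 3,
                         ga = ga_config(m_start = 2, m_end = 4, pop = 10,
                                        generations = 8, k = 5, seed = 7),
                         seed = 7)
    }
    cache
  }
})

test_that("the fitted ensemble reports its structure and learns the task", {
  fit <- fit_small_model()
  expect_s3_class(fit, "pepstack")
  expect_equal(nrow(fit$architecture$specs), 6L)
  expect_true(fit$ga$best$m >= 2 && fit$ga$best$m <= 4)
  expect_gte(fit$cv_report$MCC, 0.4)
  expect_output(print(fit), "baselines")
  expect_output(summary(fit), "Top baseline PFs")
})

test_that("prediction scores new peptides and ranks them consistently", {
  fit <- fit_small_model()
  new <- synth_peptides(6, 6, length_range = c(10, 20), s = 1, seed = 55)
  pred <- predict(fit, new)
  expect_equal(nrow(pred), 12L)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
  # the strong synthetic signal separates the classes on fresh data
  expect_gte(auc_midrank(new$label, pred$confidence), 0.9)
  # pfv view has one column per baseline
  expect_equal(dim(predict(fit, new, type = "pfv")), c(12L, 6L))
})

test_that("screening filters by length, deduplicates and ranks stably", {
  fit <- fit_small_model()
  cand <- peptide_set(c("s1", "s2", "s3", "s4"),
                      c("ACDEFGHK",                       # length 8: out
                        "ACDEFGHIKLMNPQR",                # 15: in
                        paste(rep("ACDEF", 12), collapse = ""),  # 60: out
                        "ACDEFGHIKLMNPQR"))               # duplicate of s2
  scr <- screen_peptides(fit, cand, length_bounds = c(10, 57))
  expect_equal(nrow(scr), 1L)
  expect_equal(scr$id, "s2")
  expect_equal(attr(scr, "n_filtered"), 2L)

  # ranking is invariant to input order; ties break by id
  many <- synth_peptides(8, 8, length_range = c(10, 20), s = 1, seed = 77)
  s1 <- screen_peptides(fit, many)
  ord <- rev(seq_len(nrow(many)))
  reordered <- many[ord, ]; class(reordered) <- class(many)
  s2 <- screen_peptides(fit, reordered)
  expect_equal(s1$id, s2$id)
  expect_equal(s1$confidence, s2$confidence)

  expect_warning(out <- screen_peptides(fit, peptide_set("x", "ACDE")),
                 "length bounds")
  expect_equal(nrow(out), 0L)
})

test_that("plotting draws the out-of-fold ROC without error", {
  fit <- fit_small_model()
  png(tempfile(fileext = ".png"))
  on.exit(dev.off())
  pts <- plot(fit)
  expect_true(all(c("fpr", "tpr") %in% names(pts)))
})
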