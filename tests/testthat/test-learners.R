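test_that("published hyperparameter grids are encoded verbatim", {
  expect_equal(learner_grid("SVMLN")$cost, c(1, 2, 4, 8, 16, 32))
  expect_equal(learner_grid("SVMRBF")$cost, 2^(-4:4))
  expect_equal(learner_grid("RF")$n_estimators, c(20L, 50L, 100L, 200L, 500L))
  expect_equal(learner_grid("LR")$cost, c(0.001, 0.01, 0.1, 1, 10, 100))
  for (alg in c("ADA", "ET", "LGBM", "XGB"))
    expect_equal(learner_grid(alg)$n_estimators, c(20L, 50L, 100L, 200L, 500L))
  expect_equal(learner_grid("MLP")$hidden_layer_sizes,
               c(20L, 50L, 100L, 200L, 500L))
  for (alg in c("DT", "KNN", "NB", "PLS")) expect_null(learner_grid(alg))
  expect_length(learner_names(), 13L)
})

test_that("tuning recovers a large-margin problem and stays in the grid", {
  sp <- synth_planted_pfv(200, 10, 10, shift = 0.45, seed = 31)
  m <- tune_and_fit("LR", sp$X, sp$y, k = 10, seed = 1)
  expect_gte(m$cv_mcc, 0.9)
  expect_true(m$params$cost %in% learner_grid("LR")$cost)
  # reproducibility of the tuning decision
  m2 <- tune_and_fit("LR", sp$X, sp$y, k = 10, seed = 1)
  expect_identical(m$params, m2$params)
  expect_equal(m$cv_mcc, m2$cv_mcc)
})

test_that("every algorithm fits and emits confidences in [0,1]", {
  ds <- tiny_labeled_set(25, 25, seed = 8)
  X <- encode_features(ds, "AAC")
  y <- ds$label
  # tuned learners exercised at a single grid point through the shared
  # backend contract; cheap learners through the public tuner
  for (alg in c("DT", "KNN", "NB", "PLS", "LR", "SVMLN", "SVMRBF")) {
    m <- tune_and_fit(alg, X, y, k = 3, seed = 2)
    cf <- predict_confidence(m, X)
    expect_true(all(cf >= 0 & cf <= 1), info = alg)
    expect_equal(cf[1], predict_confidence(m, X[c(1, 1), ])[2],
                 info = alg)              # duplicate rows agree
  }
  for (alg in c("ADA", "ET", "LGBM", "RF", "XGB", "MLP")) {
    backend <- pepstack:::.learner_backend(alg)
    params <- list(n_estimators = 30L, hidden_layer_sizes = 10L)
    y01 <- as.integer(y == "positive")
    mod <- backend$fit(X, y01, params, 2L)
    cf <- pmin(pmax(backend$predict(mod, X), 0), 1)
    expect_true(all(cf >= 0 & cf <= 1), info = alg)
    expect_gte(auc_midrank(y01, cf), 0.8)  # learnable signal learned
  }
})

test_that("a leaked label column yields a near-perfect learner", {
  ds <- tiny_labeled_set(50, 50, seed = 9)
  y01 <- as.integer(ds$label == "positive")
  X <- cbind(encode_features(ds, "AAC"), leak = y01)
  m <- tune_and_fit("LR", X, ds$label, k = 5, seed = 3)
  expect_gte(auc_midrank(y01, predict_confidence(m, X)), 0.99)
})

test_that("dimension mismatches and degenerate labels are rejected", {
  ds <- tiny_labeled_set(10, 10)
  X <- encode_features(ds, "AAC")
  expect_error(tune_and_fit("LR", X, rep("positive", 20), k = 3),
               "both classes")
  m <- tune_and_fit("NB", X, ds$label, k = 3, seed = 1)
  expect_error(predict_confidence(m, X[, 1:5]), "dimension")
})
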