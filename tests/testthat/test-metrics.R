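test_that("confusion-based metrics follow their definitions", {
  # perfect two-sample classifier
  r <- score(c(1, 0), c(0.9, 0.1))
  expect_equal(r$MCC, 1)
  expect_equal(r$ACC, 1)
  expect_equal(c(r$TP, r$TN, r$FP, r$FN), c(1L, 1L, 0L, 0L))

  # constructed confusion: 27 positives all found, 5 of 57 negatives missed
  y <- rep(c(1, 0), c(27, 57))
  conf <- c(rep(0.9, 27), rep(0.8, 5), rep(0.1, 52))
  r2 <- score(y, conf)
  expect_equal(r2$Sn, 1)
  expect_equal(r2$Sp, 52 / 57)
  expect_equal(r2$BACC, (r2$Sn + r2$Sp) / 2)
  expect_equal(round(r2$Sp, 3), 0.912)
  expect_equal(round(r2$BACC, 3), 0.956)

  # all-positive predictions on a mixed set: zero denominator -> MCC 0
  r3 <- score(c(1, 0, 1), c(0.9, 0.9, 0.9))
  expect_equal(r3$MCC, 0)
  expect_equal(r3$Sp, 0)

  # threshold ties go to the positive class
  r4 <- score(c(1, 0), c(0.5, 0.4), threshold = 0.5)
  expect_equal(r4$TP, 1L)
  expect_error(score(numeric(0), numeric(0)), "empty")
})

test_that("BACC identity holds on random reports", {
  set.seed(17)
  for (i in 1:20) {
    y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    r <- score(y, runif(50))
    expect_equal(r$BACC, (r$Sn + r$Sp) / 2)
    expect_equal(r$TP + r$TN + r$FP + r$FN, r$n)
  }
})

test_that("midrank AUC matches brute force and is rank-invariant", {
  set.seed(23)
  y <- rbinom(60, 1, 0.5)
  conf <- round(runif(60), 1)            # force ties
  expect_equal(auc_midrank(y, conf), oracle_auc(y, conf))
  # strictly monotone transform leaves AUC unchanged
  expect_equal(auc_midrank(y, conf), auc_midrank(y, exp(3 * conf) - 1))
  # constant confidences score exactly one half
  expect_equal(auc_midrank(y, rep(0.7, 60)), 0.5)
})

test_that("stratified folds cover all samples with both classes", {
  y <- rep(c(1, 0), c(30, 70))
  folds <- make_folds(y, 10, seed = 3)
  expect_setequal(unique(folds), 1:10)
  for (f in 1:10) expect_setequal(unique(y[folds == f]), c(0, 1))
  expect_identical(folds, make_folds(y, 10, seed = 3))
})

test_that("pooled cross-validation handles perfect, constant and null pipelines", {
  set.seed(4)
  X <- matrix(rnorm(200 * 5), 200)
  y <- rbinom(200, 1, 0.5)
  leak_fit <- function(X, y01) y01
  # perfect pipeline: confidence = held-out label (via an X column)
  Xp <- cbind(X, y)
  r <- cross_validate(Xp, y, fit = function(X, y01) NULL,
                      predict_fn = function(m, X) X[, 6], k = 5, seed = 1)
  expect_equal(r$MCC, 1)
  expect_equal(r$AUC, 1)
  # constant pipeline: midrank ties give AUC 0.5
  r2 <- cross_validate(X, y, fit = function(X, y01) NULL,
                       predict_fn = function(m, X) rep(0.5, nrow(X)),
                       k = 5, seed = 1)
  expect_equal(r2$AUC, 0.5)
  # permuted labels: a real learner scores near zero MCC
  yperm <- sample(y)
  r3 <- cross_validate(Xp, yperm,
                       fit = function(X, y01) pls1_fit(X[, 1:5], y01, 2),
                       predict_fn = function(m, X)
                         pmin(pmax(predict(m, X[, 1:5]), 0), 1),
                       k = 5, seed = 2)
  expect_lte(abs(r3$MCC), 0.15)
})

test_that("ROC points run from the origin to (1,1)", {
  y <- c(1, 1, 0, 0, 1)
  pts <- roc_points(y, c(0.9, 0.7, 0.6, 0.2, 0.1))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})
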