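# The 13 baseline learning algorithms.  Nine carry hyperparameter
# grids tuned by stratified cross-validated MCC; DT, KNN, NB and PLS
# run with documented fixed defaults.  Every learner exposes the same
# contract: fit on (X, y01, params, seed), then emit a positive-class
# confidence in [0,1] for new rows.  Margin-only learners are mapped
# into [0,1] monotonically (SVMs by Platt calibration inside the SVM
# backend, PLS by clipping the predicted response, boosting by an
# affine map of the normalised margin).

#' Names of the 13 baseline learning algorithms
#' @return Character vector: ADA, DT, ET, KNN, LGBM, LR, MLP, NB, PLS,
#'   RF, SVMLN, SVMRBF, XGB.
#' @export
learner_names <- function() {
  c("ADA", "DT", "ET", "KNN", "LGBM", "LR", "MLP", "NB", "PLS",
    "RF", "SVMLN", "SVMRBF", "XGB")
}

#' Hyperparameter grid of a learner
#'
#' The nine tuned algorithms carry their published grids (tree/round
#' counts 20-500, LR cost 0.001-100, linear-SVM cost 2^0..2^5, RBF-SVM
#' cost 2^-4..2^4, MLP hidden sizes 20-500); DT, KNN, NB and PLS return
#' NULL (fixed defaults: KNN k = 5, PLS 2 components, library defaults
#' otherwise).
#'
#' @param algorithm Learner name, see [learner_names()].
#' @return Named list of candidate values, or NULL for untuned
#'   learners.
#' @export
learner_grid <- function(algorithm) {
  algorithm <- match.arg(algorithm, learner_names())
  counts <- c(20L, 50L, 100L, 200L, 500L)
  switch(algorithm,
         ADA = list(n_estimators = counts),
         ET = list(n_estimators = counts),
         LGBM = list(n_estimators = counts),
         LR = list(cost = c(0.001, 0.01, 0.1, 1, 10, 100)),
         MLP = list(hidden_layer_sizes = counts),
         RF = list(n_estimators = counts),
         SVMLN = list(cost = 2^(0:5)),
         SVMRBF = list(cost = 2^(-4:4)),
         XGB = list(n_estimators = counts),
         NULL)
}

# default parameters for the untuned learners
.learner_defaults <- function(algorithm) {
  switch(algorithm,
         KNN = list(k = 5L),
         PLS = list(ncomp = 2L),
         list())
}

# ---- individual fit / predict backends ------------------------------

.fit_ada <- function(X, y01, params, seed) {
  n_est <- params$n_estimators
  n <- nrow(X)
  df <- data.frame(X)
  names(df) <- paste0(".f", seq_len(ncol(X)))
  df$.y <- factor(y01, levels = c(0L, 1L))
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1L, cp = -1, minsplit = 2L,
                               xval = 0L)
  for (m in seq_len(n_est)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    h <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w * (h != y01))
    if (err <= 1e-12) { stumps[[m]] <- fit; alphas[m] <- 10; break }
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[m]] <- fit; alphas[m] <- alpha
    w <- w * exp(alpha * (h != y01))
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {            # unlearnable: constant model
    stumps <- list(NULL); alphas <- 1
  }
  list(stumps = stumps, alphas = alphas, p = ncol(X),
       base_rate = mean(y01))
}

.predict_ada <- function(model, X) {
  df <- data.frame(X)
  names(df) <- paste0(".f", seq_len(ncol(X)))
  if (is.null(model$stumps[[1]])) return(rep(model$base_rate, nrow(X)))
  f <- rep(0, nrow(X))
  for (m in seq_along(model$stumps)) {
    h <- as.integer(as.character(predict(model$stumps[[m]], df,
                                         type = "class")))
    f <- f + model$alphas[m] * (2 * h - 1)
  }
  (f / sum(model$alphas) + 1) / 2
}

.fit_dt <- function(X, y01, params, seed) {
  df <- data.frame(X)
  names(df) <- paste0(".f", seq_len(ncol(X)))
  df$.y <- factor(y01, levels = c(0L, 1L))
  rpart::rpart(.y ~ ., data = df, method = "class")
}

.predict_dt <- function(model, X) {
  df <- data.frame(X)
  names(df) <- paste0(".f", seq_len(ncol(X)))
  unname(predict(model, df, type = "prob")[, "1"])
}

.fit_ranger <- function(X, y01, params, seed, extratrees = FALSE) {
  args <- list(x = X, y = factor(y01, levels = c(0L, 1L)),
               probability = TRUE, num.trees = params$n_estimators,
               seed = seed, num.threads = 1L)
  if (extratrees) {
    args$splitrule <- "extratrees"
    args$num.random.splits <- 1L
  }
  do.call(ranger::ranger, args)
}

.predict_ranger <- function(model, X) {
  unname(predict(model, data = X, num.threads = 1L)$predictions[, "1"])
}

.fit_knn <- function(X, y01, params, seed) {
  list(X = X, y01 = y01, k = params$k, seed = seed)
}

.predict_knn <- function(model, X) {
  cl <- factor(model$y01, levels = c(0L, 1L))
  pred <- .with_seed(model$seed,
    class::knn(model$X, X, cl, k = model$k, prob = TRUE, use.all = TRUE))
  p_win <- attr(pred, "prob")
  ifelse(pred == "1", p_win, 1 - p_win)
}

.xgb_train <- function(X, y01, nrounds, seed, lossguide = FALSE) {
  params <- list(objective = "binary:logistic", nthread = 1L,
                 seed = seed, verbosity = 0L)
  if (lossguide) {
    params$tree_method <- "hist"
    params$grow_policy <- "lossguide"
    params$max_leaves <- 31L
    params$max_depth <- 0L
    params$eta <- 0.1
  }
  dtrain <- xgboost::xgb.DMatrix(X, label = y01, nthread = 1L)
  .with_seed(seed,
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                       verbose = 0L))
}

.predict_xgb <- function(model, X) {
  predict(model, xgboost::xgb.DMatrix(X, nthread = 1L))
}

.fit_lr <- function(X, y01, params, seed) {
  Xf <- if (ncol(X) < 2L) cbind(X, .dummy = 0) else X
  # sklearn-style cost C maps to ridge penalty lambda = 1 / (C * n)
  glmnet::glmnet(Xf, factor(y01, levels = c(0L, 1L)), family = "binomial",
                 alpha = 0, lambda = 1 / (params$cost * nrow(X)),
                 standardize = FALSE)
}

.predict_lr <- function(model, X) {
  Xf <- if (ncol(X) < 2L) cbind(X, .dummy = 0) else X
  drop(predict(model, Xf, type = "response"))
}

.fit_mlp <- function(X, y01, params, seed) {
  .with_seed(seed,
    nnet::nnet(x = X, y = y01, size = params$hidden_layer_sizes,
               entropy = TRUE, decay = 1e-4, maxit = 200L,
               MaxNWts = 1e7, trace = FALSE))
}

.predict_mlp <- function(model, X) {
  pmin(pmax(drop(predict(model, X)), 0), 1)
}

.fit_nb <- function(X, y01, params, seed) {
  m <- e1071::naiveBayes(x = as.data.frame(X),
                         y = factor(y01, levels = c(0L, 1L)))
  # floor the per-class Gaussian sd so constant features cannot produce
  # infinite densities
  m$tables <- lapply(m$tables, function(tb) {
    tb[, 2] <- pmax(tb[, 2], 1e-6)
    tb
  })
  m
}

.predict_nb <- function(model, X) {
  unname(predict(model, as.data.frame(X), type = "raw")[, "1"])
}

.fit_pls_learner <- function(X, y01, params, seed) {
  pls1_fit(X, y01, ncomp = params$ncomp)
}

.fit_svm <- function(X, y01, params, seed, kernel) {
  .with_seed(seed,
    e1071::svm(x = X, y = factor(y01, levels = c(0L, 1L)),
               kernel = kernel, cost = params$cost, probability = TRUE,
               scale = FALSE))
}

.predict_svm <- function(model, X) {
  p <- predict(model, X, probability = TRUE)
  unname(attr(p, "probabilities")[, "1"])
}

# registry: algorithm -> fit(X, y01, params, seed) + predict(model, X)
.learner_backend <- function(algorithm) {
  switch(algorithm,
    ADA = list(fit = .fit_ada, predict = .predict_ada),
    DT = list(fit = .fit_dt, predict = .predict_dt),
    ET = list(fit = function(X, y, p, s) .fit_ranger(X, y, p, s, TRUE),
              predict = .predict_ranger),
    KNN = list(fit = .fit_knn, predict = .predict_knn),
    LGBM = list(fit = function(X, y, p, s)
                  .xgb_train(X, y, p$n_estimators, s, lossguide = TRUE),
                predict = .predict_xgb),
    LR = list(fit = .fit_lr, predict = .predict_lr),
    MLP = list(fit = .fit_mlp, predict = .predict_mlp),
    NB = list(fit = .fit_nb, predict = .predict_nb),
    PLS = list(fit = .fit_pls_learner,
               predict = function(m, X) .pls_confidence(m, X)),
    RF = list(fit = function(X, y, p, s) .fit_ranger(X, y, p, s, FALSE),
              predict = .predict_ranger),
    SVMLN = list(fit = function(X, y, p, s) .fit_svm(X, y, p, s, "linear"),
                 predict = .predict_svm),
    SVMRBF = list(fit = function(X, y, p, s) .fit_svm(X, y, p, s, "radial"),
                  predict = .predict_svm),
    XGB = list(fit = function(X, y, p, s) .xgb_train(X, y, p$n_estimators, s),
               predict = .predict_xgb),
    stop("unknown algorithm: ", algorithm))
}

# ---- tuning ---------------------------------------------------------

.grid_points <- function(grid) {
  if (is.null(grid)) return(list(list()))
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

#' Grid-tune a learner by cross-validated MCC and refit on all data
#'
#' For every grid point the stratified k-fold out-of-fold confidences
#' are pooled and scored by MCC; the maximising point (first in grid
#' order on ties, i.e. the smallest candidate) is refitted on the full
#' data.  Untuned learners (DT, KNN, NB, PLS) skip the search and fit
#' their fixed defaults directly.
#'
#' @param algorithm Learner name, see [learner_names()].
#' @param X Feature matrix.
#' @param y Binary labels (both classes required).
#' @param k Tuning folds (default 10).
#' @param seed Integer seed (folds and stochastic learners).
#' @return A `trained_learner` with fields algorithm, params, cv_mcc
#'   (NA for untuned learners), model, features.
#' @export
tune_and_fit <- function(algorithm, X, y, k = 10L, seed = 1L) {
  algorithm <- match.arg(algorithm, learner_names())
  X <- as.matrix(X)
  y01 <- .as_y01(y)
  if (length(unique(y01)) < 2L) stop("y must contain both classes")
  if (!all(is.finite(X))) stop("non-finite feature values")
  backend <- .learner_backend(algorithm)
  grid <- learner_grid(algorithm)
  cands <- .grid_points(grid)
  best <- NULL
  if (length(cands) > 1L) {
    folds <- make_folds(y01, k, seed)
    for (i in seq_along(cands)) {
      params <- c(cands[[i]], .learner_defaults(algorithm))
      oof <- rep(NA_real_, length(y01))
      for (f in sort(unique(folds))) {
        tr <- folds != f
        m <- backend$fit(X[tr, , drop = FALSE], y01[tr], params,
                         seed + 1000L * f)
        oof[!tr] <- backend$predict(m, X[!tr, , drop = FALSE])
      }
      mcc <- score(y01, oof, protocol = "tuning")$MCC
      if (is.null(best) || mcc > best$mcc) best <- list(params = params,
                                                        mcc = mcc)
    }
  } else {
    best <- list(params = c(cands[[1]], .learner_defaults(algorithm)),
                 mcc = NA_real_)
  }
  model <- backend$fit(X, y01, best$params, seed)
  structure(list(algorithm = algorithm, params = best$params,
                 cv_mcc = best$mcc, model = model,
                 features = colnames(X), p = ncol(X), seed = seed),
            class = "trained_learner")
}

#' Positive-class confidence of a trained learner
#'
#' @param m A `trained_learner` from [tune_and_fit()].
#' @param X Feature matrix with the training dimension.
#' @return Numeric vector of confidences in [0, 1].
#' @export
predict_confidence <- function(m, X) {
  stopifnot(inherits(m, "trained_learner"))
  X <- as.matrix(X)
  if (ncol(X) != m$p)
    stop("feature dimension ", ncol(X), " does not match training (", m$p, ")")
  if (!is.null(m$features) && !is.null(colnames(X)))
    X <- X[, m$features, drop = FALSE]
  conf <- .learner_backend(m$algorithm)$predict(m$model, X)
  pmin(pmax(as.numeric(conf), 0), 1)
}

#' @export
print.trained_learner <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat("trained_learner ", x$algorithm, " (", x$p, " features",
      if (nzchar(ps)) paste0("; ", ps), ")",
      if (!is.na(x$cv_mcc)) sprintf("; tuning CV MCC %.3f", x$cv_mcc),
      "\n", sep = "")
  invisible(x)
}
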