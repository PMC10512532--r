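# Evaluation harness: confusion counts, ACC/BACC/Sn/Sp/MCC, midrank
# AUC, stratified folds, pooled cross-validation.

#' Stratified k-fold assignment
#'
#' @param y Binary labels (factor, 0/1 or logical; the positive class
#'   is the second factor level or 1/TRUE).
#' @param k Number of folds (>= 2); every fold receives samples of both
#'   classes whenever class sizes allow.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @export
make_folds <- function(y, k, seed) {
  y01 <- .as_y01(y)
  stopifnot(k >= 2L)
  if (min(table(y01)) < k)
    warning("a class has fewer samples than folds; some folds will miss it")
  folds <- integer(length(y01))
  .with_seed(seed, {
    for (cl in unique(y01)) {
      idx <- sample(which(y01 == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

.as_y01 <- function(y) {
  if (is.factor(y)) return(as.integer(y == levels(y)[2L]))
  if (is.logical(y)) return(as.integer(y))
  if (is.character(y)) return(as.integer(.coerce_label(y) == "positive"))
  stopifnot(all(y %in% c(0, 1)))
  as.integer(y)
}

#' Classification metrics from labels and confidences
#'
#' Thresholds the confidences into classes (ties at the threshold are
#' positive) and computes ACC, BACC = (Sn+Sp)/2, Sn, Sp, MCC and the
#' midrank (Mann-Whitney) AUC, plus the confusion counts.  Degenerate
#' denominators (MCC with an empty margin, Sn/Sp with an absent class)
#' are reported as 0 so broken models score poorly instead of crashing.
#'
#' @param y_true Binary labels.
#' @param confidence Numeric confidences, higher = more positive.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @param protocol Tag recorded in the report ("cross-validation",
#'   "independent", ...).
#' @return An `eval_report` list: ACC, BACC, Sn, Sp, MCC, AUC, TP, TN,
#'   FP, FN, n, threshold, protocol.
#' @export
score <- function(y_true, confidence, threshold = 0.5,
                  protocol = "independent") {
  y01 <- .as_y01(y_true)
  if (length(y01) == 0L) stop("empty input")
  stopifnot(length(y01) == length(confidence), all(is.finite(confidence)))
  pred <- as.integer(confidence >= threshold)
  tp <- sum(pred == 1L & y01 == 1L); tn <- sum(pred == 0L & y01 == 0L)
  fp <- sum(pred == 1L & y01 == 0L); fn <- sum(pred == 0L & y01 == 1L)
  sn <- if (tp + fn > 0L) tp / (tp + fn) else 0
  sp <- if (tn + fp > 0L) tn / (tn + fp) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  out <- list(ACC = (tp + tn) / length(y01), BACC = (sn + sp) / 2,
              Sn = sn, Sp = sp, MCC = mcc,
              AUC = auc_midrank(y01, confidence),
              TP = tp, TN = tn, FP = fp, FN = fn,
              n = length(y01), threshold = threshold, protocol = protocol)
  class(out) <- "eval_report"
  out
}

#' Midrank AUC (Mann-Whitney statistic)
#'
#' Rank-based area under the ROC curve; tied confidences receive
#' midranks, so a constant classifier scores exactly 0.5.
#' @param y_true Binary labels.
#' @param confidence Numeric confidences.
#' @return AUC in [0, 1]; NA if a class is absent.
#' @export
auc_midrank <- function(y_true, confidence) {
  y01 <- .as_y01(y_true)
  n1 <- sum(y01 == 1L); n0 <- sum(y01 == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(confidence)                       # midranks on ties
  (sum(r[y01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s] n=%d  (TP %d, TN %d, FP %d, FN %d)\n",
              x$protocol, x$n, x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  ACC %.3f  BACC %.3f  Sn %.3f  Sp %.3f  MCC %.3f  AUC %.3f\n",
              x$ACC, x$BACC, x$Sn, x$Sp, x$MCC, x$AUC))
  invisible(x)
}

#' One-row data.frame view of an eval_report (Table-style column order)
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return data.frame with columns ACC, BACC, Sn, Sp, MCC, AUC.
#' @export
as.data.frame.eval_report <- function(x, ...) {
  data.frame(ACC = x$ACC, BACC = x$BACC, Sn = x$Sn, Sp = x$Sp,
             MCC = x$MCC, AUC = x$AUC)
}

#' Pooled k-fold cross-validation of an arbitrary fit/predict pair
#'
#' Fits on each training fold and predicts the held-out fold;
#' out-of-fold confidences are pooled into a single report (one row per
#' model), the aggregation used throughout the package.
#'
#' @param X Feature matrix (samples x features).
#' @param y Binary labels.
#' @param fit `function(X, y01)` returning a fitted model.
#' @param predict_fn `function(model, X)` returning confidences.
#' @param k Folds (default 10).
#' @param seed Integer seed for the stratified fold assignment.
#' @param threshold Decision threshold for the pooled report.
#' @return An `eval_report` with protocol "cross-validation" and an
#'   attribute `oof` holding the pooled out-of-fold confidences.
#' @export
cross_validate <- function(X, y, fit, predict_fn, k = 10L, seed = 1L,
                           threshold = 0.5) {
  y01 <- .as_y01(y)
  X <- as.matrix(X)
  folds <- make_folds(y01, k, seed)
  oof <- rep(NA_real_, length(y01))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y01[tr])) < 2L)
      stop("fold construction left a training fold single-class")
    m <- fit(X[tr, , drop = FALSE], y01[tr])
    oof[!tr] <- predict_fn(m, X[!tr, , drop = FALSE])
  }
  rep <- score(y01, oof, threshold = threshold, protocol = "cross-validation")
  attr(rep, "oof") <- oof
  rep
}

#' ROC curve points from labels and confidences
#'
#' @param y_true Binary labels.
#' @param confidence Numeric confidences.
#' @return data.frame with columns threshold, fpr, tpr, ordered for
#'   plotting from (0,0) to (1,1).
#' @export
roc_points <- function(y_true, confidence) {
  y01 <- .as_y01(y_true)
  thr <- c(Inf, sort(unique(confidence), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- confidence >= t
    c(fpr = sum(pred & y01 == 0L) / max(sum(y01 == 0L), 1L),
      tpr = sum(pred & y01 == 1L) / max(sum(y01 == 1L), 1L))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}
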