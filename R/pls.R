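# Partial least squares regression (PLS1, NIPALS) on a 0/1 response.
# This is the package's own implementation: it backs both the PLS
# baseline learner and the meta-classifier, and is verified against an
# independent PLS implementation in the test suite.

#' Fit univariate partial least squares regression
#'
#' NIPALS PLS1 on mean-centred predictors and response.  Extraction
#' stops early (with fewer components) when the residual covariance
#' vanishes, so `ncomp` is an upper bound on degenerate inputs.
#'
#' @param X Numeric matrix (samples x features), no missing values.
#' @param y Numeric response (here: class labels coded 0/1).
#' @param ncomp Number of latent components (capped at ncol(X)).
#' @return A `pls1_fit` list with `coef` (per-feature regression
#'   weights), `intercept`, `ncomp` (components actually used) and the
#'   training feature names.
#' @export
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  ncomp <- max(1L, min(as.integer(ncomp), ncol(X)))
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pa <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pa)
    yc <- yc - t * qa
    W[, a] <- w; P[, a] <- pa; Q[a] <- qa
    used <- a
  }
  if (used == 0L) {
    coef <- rep(0, p)
  } else {
    Wu <- W[, seq_len(used), drop = FALSE]
    Pu <- P[, seq_len(used), drop = FALSE]
    coef <- drop(Wu %*% solve(crossprod(Pu, Wu), Q[seq_len(used)]))
  }
  feats <- colnames(X)
  if (!is.null(feats) && !all(nzchar(feats))) feats <- NULL
  structure(list(coef = coef, intercept = ym - sum(xm * coef),
                 ncomp = used, features = feats),
            class = "pls1_fit")
}

#' Predict from a PLS1 fit
#' @param object A `pls1_fit`.
#' @param newdata Matrix with the training columns (matched by name
#'   when both sides are named).
#' @param ... Unused.
#' @return Numeric predicted response (unclipped).
#' @export
predict.pls1_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(newdata))) {
    if (!all(object$features %in% colnames(newdata)))
      stop("newdata is missing columns: ",
           paste(setdiff(object$features, colnames(newdata)), collapse = ", "))
    newdata <- newdata[, object$features, drop = FALSE]
  }
  if (ncol(newdata) != length(object$coef))
    stop("newdata has ", ncol(newdata), " columns, fit used ",
         length(object$coef))
  drop(newdata %*% object$coef) + object$intercept
}

# PLS response clipped into [0,1]: the confidence convention used by
# both the PLS baseline learner and the meta-model
.pls_confidence <- function(fit, X) {
  pmin(pmax(predict(fit, X), 0), 1)
}
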