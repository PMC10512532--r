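# Stacking layer: the cross-product of encoders and algorithms defines
# the baseline zoo; out-of-fold predicted confidences of every baseline
# form the probabilistic feature vector (PFV); a PLS classifier over
# (selected) PFV columns is the meta-model.

#' Define a stacking architecture
#'
#' @param encoders Ordered encoder names (default: all 10).
#' @param algorithms Ordered algorithm names (default: all 13, giving
#'   130 baseline specs).
#' @return A `stack_architecture` with the spec table (one row per
#'   (encoder, algorithm) pair, column name "<ALG>-<ENC>").
#' @export
stack_architecture <- function(encoders = encoder_names(),
                               algorithms = learner_names()) {
  encoders <- vapply(encoders, match.arg, character(1),
                     choices = encoder_names())
  algorithms <- vapply(algorithms, match.arg, character(1),
                       choices = learner_names())
  stopifnot(!anyDuplicated(encoders), !anyDuplicated(algorithms))
  specs <- expand.grid(algorithm = algorithms, encoder = encoders,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  specs$column <- paste0(specs$algorithm, "-", specs$encoder)
  structure(list(encoders = unname(encoders),
                 algorithms = unname(algorithms), specs = specs),
            class = "stack_architecture")
}

#' @export
print.stack_architecture <- function(x, ...) {
  cat("stack_architecture: ", length(x$encoders), " encoders x ",
      length(x$algorithms), " algorithms = ", nrow(x$specs),
      " baseline models\n", sep = "")
  invisible(x)
}

# encode the dataset once per encoder
.encode_all <- function(arch, ds, encoder_args = list()) {
  out <- lapply(arch$encoders, function(enc)
    do.call(encode_features, c(list(ds, enc), encoder_args[[enc]])))
  names(out) <- arch$encoders
  out
}

#' Build the out-of-fold probabilistic feature vector matrix
#'
#' One stratified k-fold partition is fixed for the whole architecture;
#' for every (encoder, algorithm) spec and every fold, the learner is
#' tuned and fitted on the in-fold samples only and its confidences
#' fill the held-out rows.  Each training sample therefore receives one
#' out-of-fold confidence per baseline model, which is what keeps the
#' meta-model free of memorisation leakage.
#'
#' @param arch A `stack_architecture`.
#' @param ds Labeled `peptide_set`.
#' @param k Folds (default 10).
#' @param seed Integer seed (fold partition and learner seeds).
#' @param tune_per_fold Re-tune hyperparameters inside every fold
#'   (default TRUE); FALSE tunes once on the full training data first,
#'   which is cheaper but lets tuning see the held-out labels.
#' @param tune_k Folds of the inner tuning CV (default `k`).
#' @param encoder_args Optional named list (per encoder) of extra
#'   encoder arguments.
#' @return Numeric matrix samples x baselines (values in [0,1]),
#'   columns named "<ALG>-<ENC>", with attributes `provenance`
#'   ("out_of_fold"), `folds` and `y`.
#' @export
build_training_pfv <- function(arch, ds, k = 10L, seed = 1L,
                               tune_per_fold = TRUE, tune_k = k,
                               encoder_args = list()) {
  stopifnot(inherits(arch, "stack_architecture"),
            inherits(ds, "peptide_set"), !is.null(ds$label), k >= 2L)
  y01 <- .as_y01(ds$label)
  if (length(unique(y01)) < 2L) stop("both classes required")
  feats <- .encode_all(arch, ds, encoder_args)
  folds <- make_folds(y01, k, seed)
  pfv <- matrix(NA_real_, nrow(ds), nrow(arch$specs),
                dimnames = list(ds$id, arch$specs$column))
  for (i in seq_len(nrow(arch$specs))) {
    enc <- arch$specs$encoder[i]; alg <- arch$specs$algorithm[i]
    X <- feats[[enc]]
    fixed_params <- NULL
    if (!tune_per_fold) {
      fixed_params <- tune_and_fit(alg, X, y01, k = tune_k,
                                   seed = seed + i)$params
    }
    for (f in sort(unique(folds))) {
      tr <- folds != f
      res <- try({
        if (is.null(fixed_params)) {
          m <- tune_and_fit(alg, X[tr, , drop = FALSE], y01[tr],
                            k = tune_k, seed = seed + i + 7919L * f)
          pfv[!tr, i] <- predict_confidence(m, X[!tr, , drop = FALSE])
        } else {
          backend <- .learner_backend(alg)
          mm <- backend$fit(X[tr, , drop = FALSE], y01[tr], fixed_params,
                            seed + i + 7919L * f)
          conf <- backend$predict(mm, X[!tr, , drop = FALSE])
          pfv[!tr, i] <- pmin(pmax(as.numeric(conf), 0), 1)
        }
      }, silent = TRUE)
      if (inherits(res, "try-error"))
        stop("baseline fit failed for (", enc, ", ", alg, "): ",
             attr(res, "condition")$message)
    }
  }
  attr(pfv, "provenance") <- "out_of_fold"
  attr(pfv, "folds") <- folds
  attr(pfv, "y") <- y01
  pfv
}

#' Tune and fit every baseline on the full training data
#'
#' These full-data baselines serve external prediction (independent
#' test sets and screening); their column order matches the training
#' PFV.
#'
#' @inheritParams build_training_pfv
#' @return List of `trained_learner`s named by PFV column.
#' @export
fit_full_baselines <- function(arch, ds, tune_k = 10L, seed = 1L,
                               encoder_args = list()) {
  stopifnot(inherits(arch, "stack_architecture"), !is.null(ds$label))
  y01 <- .as_y01(ds$label)
  feats <- .encode_all(arch, ds, encoder_args)
  models <- vector("list", nrow(arch$specs))
  names(models) <- arch$specs$column
  for (i in seq_len(nrow(arch$specs))) {
    enc <- arch$specs$encoder[i]; alg <- arch$specs$algorithm[i]
    models[[i]] <- tune_and_fit(alg, feats[[enc]], y01, k = tune_k,
                                seed = seed + i)
  }
  models
}

#' Apply full-data baselines to new peptides
#'
#' @param arch The `stack_architecture` the baselines came from.
#' @param baselines List from [fit_full_baselines()].
#' @param ds `peptide_set` (labels optional).
#' @param encoder_args As in [build_training_pfv()].
#' @return PFV matrix with columns aligned to the training PFV and
#'   provenance "full_model".
#' @export
build_external_pfv <- function(arch, baselines, ds, encoder_args = list()) {
  stopifnot(inherits(arch, "stack_architecture"),
            identical(names(baselines), arch$specs$column))
  feats <- .encode_all(arch, ds, encoder_args)
  pfv <- matrix(NA_real_, nrow(ds), nrow(arch$specs),
                dimnames = list(ds$id, arch$specs$column))
  for (i in seq_len(nrow(arch$specs))) {
    enc <- arch$specs$encoder[i]
    pfv[, i] <- predict_confidence(baselines[[i]], feats[[enc]])
  }
  attr(pfv, "provenance") <- "full_model"
  pfv
}

#' Fit the PLS meta-classifier on (selected) PFV columns
#'
#' PLS regression of the 0/1 labels on the masked PFV columns; the
#' classifier thresholds the clipped response (default 0.5, ties
#' positive).  When `ncomp` is NULL the component count is chosen from
#' 1..min(8, m) by stratified k-fold CV MCC.
#'
#' @param pfv PFV matrix (training rows must be out-of-fold).
#' @param y Binary labels.
#' @param mask Logical/integer column selector (default: all columns —
#'   the full-PFV control model).
#' @param ncomp Component count, or NULL to select by CV.
#' @param k,seed CV folds and seed for the component search.
#' @param threshold Decision threshold in (0, 1).
#' @return A `meta_model` with the mask, component count, threshold
#'   and the underlying `pls1_fit`.
#' @export
fit_meta <- function(pfv, y, mask = NULL, ncomp = NULL, k = 10L,
                     seed = 1L, threshold = 0.5) {
  pfv <- as.matrix(pfv)
  y01 <- .as_y01(y)
  if (length(unique(y01)) < 2L) stop("y must contain both classes")
  if (is.null(mask)) mask <- rep(TRUE, ncol(pfv))
  if (is.numeric(mask)) mask <- seq_len(ncol(pfv)) %in% mask
  if (!any(mask)) stop("mask selects no columns")
  stopifnot(threshold > 0, threshold < 1)
  Xs <- pfv[, mask, drop = FALSE]
  m <- ncol(Xs)
  if (is.null(ncomp)) {
    cands <- seq_len(min(8L, m))
    folds <- make_folds(y01, k, seed)
    mccs <- vapply(cands, function(nc) {
      oof <- rep(NA_real_, length(y01))
      for (f in sort(unique(folds))) {
        tr <- folds != f
        fit <- pls1_fit(Xs[tr, , drop = FALSE], y01[tr], nc)
        oof[!tr] <- .pls_confidence(fit, Xs[!tr, , drop = FALSE])
      }
      score(y01, oof, threshold = threshold, protocol = "tuning")$MCC
    }, numeric(1))
    ncomp <- cands[which.max(mccs)]
  }
  fit <- pls1_fit(Xs, y01, ncomp)
  structure(list(fit = fit, mask = mask, ncomp = ncomp,
                 threshold = threshold,
                 columns = colnames(pfv)[mask]),
            class = "meta_model")
}

#' Predict with the meta-model
#'
#' @param object A `meta_model`.
#' @param pfv PFV matrix containing the meta-model's selected columns.
#' @param ... Unused.
#' @return data.frame with columns id (when the PFV has rownames),
#'   confidence in [0,1] and class ("positive" iff confidence >=
#'   threshold).
#' @export
predict.meta_model <- function(object, pfv, ...) {
  pfv <- as.matrix(pfv)
  if (!is.null(colnames(pfv))) {
    missing <- setdiff(object$columns, colnames(pfv))
    if (length(missing))
      stop("PFV is missing columns: ", paste(missing, collapse = ", "))
    Xs <- pfv[, object$columns, drop = FALSE]
  } else {
    Xs <- pfv[, object$mask, drop = FALSE]
  }
  conf <- .pls_confidence(object$fit, Xs)
  data.frame(id = if (!is.null(rownames(pfv))) rownames(pfv)
             else seq_len(nrow(pfv)),
             confidence = unname(conf),
             class = ifelse(conf >= object$threshold, "positive",
                            "negative"),
             stringsAsFactors = FALSE)
}

#' @export
print.meta_model <- function(x, ...) {
  cat("meta_model (PLS): ", sum(x$mask), " of ", length(x$mask),
      " PFV columns, ", x$ncomp, " component(s), threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}
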