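# Top-level fitting function: encoders x learners -> out-of-fold PFV
# -> GA feature selection -> PLS meta-classifier, plus full-data
# baselines for predicting new peptides.

#' Fit a stacked ensemble peptide classifier
#'
#' Runs the full two-level pipeline on a labelled peptide dataset:
#' (1) every (encoder, algorithm) baseline is grid-tuned by CV MCC and
#' its out-of-fold confidences populate the probabilistic feature
#' vector (PFV); (2) a genetic algorithm selects a bounded subset of
#' PFV columns by CV MCC (skipped when `ga = NULL`, which keeps all
#' columns — the full-PFV control model); (3) a PLS meta-classifier is
#' fitted on the selected columns; (4) all baselines are refitted on
#' the full data so new peptides can be scored.
#'
#' @param ds Labelled `peptide_set` (both classes present).
#' @param encoders Encoder subset (default: all 10).
#' @param algorithms Algorithm subset (default: all 13).
#' @param k Folds of the out-of-fold PFV construction (default 10).
#' @param ga A [ga_config()] for PF selection, or NULL to keep the
#'   full PFV.
#' @param tune_per_fold Re-tune baseline hyperparameters inside each
#'   PFV fold (default TRUE).
#' @param tune_k Folds of the baseline tuning CV.
#' @param threshold Meta decision threshold.
#' @param seed Master integer seed.
#' @param encoder_args Optional per-encoder argument list.
#' @return A `pepstack` object; see [predict.pepstack()],
#'   [summary.pepstack()], [screen_peptides()].
#' @export
pepstack <- function(ds, encoders = encoder_names(),
                     algorithms = learner_names(), k = 10L,
                     ga = ga_config(seed = seed), tune_per_fold = TRUE,
                     tune_k = k, threshold = 0.5, seed = 1L,
                     encoder_args = list()) {
  stopifnot(inherits(ds, "peptide_set"), !is.null(ds$label))
  arch <- stack_architecture(encoders, algorithms)
  pfv <- build_training_pfv(arch, ds, k = k, seed = seed,
                            tune_per_fold = tune_per_fold,
                            tune_k = tune_k, encoder_args = encoder_args)
  y01 <- attr(pfv, "y")
  ga_res <- NULL
  if (!is.null(ga)) {
    ga_res <- select_features(pfv, y01, config = ga)
    mask <- ga_res$best$mask
    ncomp <- ga_res$best$ncomp
  } else {
    mask <- rep(TRUE, ncol(pfv))
    ncomp <- NULL                       # CV-selected inside fit_meta
  }
  meta <- fit_meta(pfv, y01, mask = mask, ncomp = ncomp, k = k,
                   seed = seed, threshold = threshold)
  cv_report <- {
    folds <- attr(pfv, "folds")
    oof <- rep(NA_real_, length(y01))
    Xs <- pfv[, mask, drop = FALSE]
    for (f in sort(unique(folds))) {
      tr <- folds != f
      fit <- pls1_fit(Xs[tr, , drop = FALSE], y01[tr], meta$ncomp)
      oof[!tr] <- .pls_confidence(fit, Xs[!tr, , drop = FALSE])
    }
    score(y01, oof, threshold = threshold, protocol = "cross-validation")
  }
  baselines <- fit_full_baselines(arch, ds, tune_k = tune_k, seed = seed,
                                  encoder_args = encoder_args)
  structure(list(architecture = arch, meta = meta, pfv = pfv,
                 ga = ga_res, baselines = baselines,
                 cv_report = cv_report, k = k, seed = seed,
                 threshold = threshold, encoder_args = encoder_args,
                 n_train = nrow(ds), call = match.call()),
            class = "pepstack")
}

#' Predict bioactivity of new peptides
#'
#' @param object A fitted `pepstack` model.
#' @param newdata A `peptide_set`, character vector of sequences, or
#'   FASTA path.
#' @param type "response" (default: data.frame of confidence and
#'   class) or "pfv" (the external baseline confidence matrix).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.pepstack <- function(object, newdata, type = c("response", "pfv"),
                             ...) {
  type <- match.arg(type)
  ds <- .as_peptide_set(newdata)
  pfv <- build_external_pfv(object$architecture, object$baselines, ds,
                            encoder_args = object$encoder_args)
  if (type == "pfv") return(pfv)
  predict(object$meta, pfv)
}

.as_peptide_set <- function(x) {
  if (inherits(x, "peptide_set")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_fasta(x))
  peptide_set(paste0("q", seq_along(x)), x)
}

#' @export
print.pepstack <- function(x, ...) {
  cat("pepstack stacked ensemble\n")
  cat("  baselines: ", length(x$architecture$encoders), " encoders x ",
      length(x$architecture$algorithms), " algorithms = ",
      nrow(x$architecture$specs), "\n", sep = "")
  cat("  meta: PLS on ", sum(x$meta$mask), " selected PF(s), ",
      x$meta$ncomp, " component(s), threshold ", x$meta$threshold,
      "\n", sep = "")
  cat("  trained on ", x$n_train, " peptides (", x$k,
      "-fold out-of-fold PFV, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.pepstack <- function(object, ...) {
  cat("Stacked ensemble peptide classifier\n\n")
  print(object$architecture)
  if (!is.null(object$ga)) {
    cat("\nGA-selected probabilistic features (", object$ga$best$m,
        "):\n  ", paste(object$ga$columns, collapse = ", "), "\n",
        sep = "")
  } else {
    cat("\nFull-PFV control model (no feature selection)\n")
  }
  cat("\nTraining cross-validation (pooled out-of-fold):\n")
  print(object$cv_report)
  y01 <- attr(object$pfv, "y")
  col_mcc <- apply(object$pfv, 2, function(cf)
    score(y01, cf, protocol = "tuning")$MCC)
  top <- sort(col_mcc, decreasing = TRUE)
  cat("\nTop baseline PFs by out-of-fold MCC:\n")
  for (i in seq_len(min(5L, length(top))))
    cat(sprintf("  %-18s %.3f\n", names(top)[i], top[i]))
  invisible(object)
}

#' ROC curve of the training out-of-fold meta predictions
#'
#' @param x A fitted `pepstack`.
#' @param ... Passed to [plot()].
#' @return The ROC points, invisibly.
#' @export
plot.pepstack <- function(x, ...) {
  y01 <- attr(x$pfv, "y")
  folds <- attr(x$pfv, "folds")
  Xs <- x$pfv[, x$meta$mask, drop = FALSE]
  oof <- rep(NA_real_, length(y01))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- pls1_fit(Xs[tr, , drop = FALSE], y01[tr], x$meta$ncomp)
    oof[!tr] <- .pls_confidence(fit, Xs[!tr, , drop = FALSE])
  }
  pts <- roc_points(y01, oof)
  plot(pts$fpr, pts$tpr, type = "l", xlab = "1 - Sp", ylab = "Sn",
       main = sprintf("Out-of-fold ROC (AUC %.3f)",
                      auc_midrank(y01, oof)), ...)
  abline(0, 1, lty = 3)
  invisible(pts)
}

#' Virtual screening: rank candidate peptides by meta confidence
#'
#' Deduplicates the candidates (exact sequences), removes peptides
#' outside the length bounds, scores the survivors with the fitted
#' model and returns them ranked by descending confidence (ties broken
#' by id for a stable order).
#'
#' @param object A fitted `pepstack` model.
#' @param newdata `peptide_set`, sequence vector or FASTA path.
#' @param length_bounds Inclusive length window (default c(10, 57)).
#' @return data.frame with columns id, sequence, length, confidence,
#'   class, rank; attribute `n_filtered` counts removed peptides.
#'   Zero survivors yield an empty data.frame with a warning.
#' @export
screen_peptides <- function(object, newdata, length_bounds = c(10L, 57L)) {
  stopifnot(inherits(object, "pepstack"))
  ds <- deduplicate(.as_peptide_set(newdata))
  len <- nchar(ds$sequence)
  keep <- len >= length_bounds[1] & len <= length_bounds[2]
  n_filtered <- sum(!keep)
  if (!any(keep)) {
    warning("no peptides within length bounds [", length_bounds[1], ", ",
            length_bounds[2], "]")
    out <- data.frame(id = character(0), sequence = character(0),
                      length = integer(0), confidence = numeric(0),
                      class = character(0), rank = integer(0))
    attr(out, "n_filtered") <- n_filtered
    return(out)
  }
  ds <- ds[keep, , drop = FALSE]
  class(ds) <- c("peptide_set", "data.frame")
  pred <- predict(object, ds)
  out <- data.frame(id = ds$id, sequence = ds$sequence,
                    length = nchar(ds$sequence),
                    confidence = pred$confidence, class = pred$class,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$confidence, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_filtered") <- n_filtered
  out
}
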