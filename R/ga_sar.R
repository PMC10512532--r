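# Genetic-algorithm feature selection (GA-SAR style): chromosomes hold
# n binary feature-inclusion genes plus one parametric gene (the PLS
# component count of the meta evaluator); fitness is stratified k-fold
# CV MCC on the masked columns; the selected feature count is repaired
# into [m_start, m_end].

#' GA feature-selection configuration
#'
#' Defaults follow the published parameterisation: selected-count
#' bounds 5-20, per-gene mutation probability 0.05, population 50.  The
#' operator suite (tournament size 3, uniform crossover, elitism 1,
#' stagnation stop after 20 generations without improvement) is this
#' package's own concrete choice and is recorded in the returned
#' object.
#'
#' @param m_start,m_end Bounds on the selected feature count.
#' @param p_m Per-gene mutation probability.
#' @param pop Population size (>= 2).
#' @param generations Generation budget (default 100).
#' @param stagnation Stop after this many generations without
#'   improvement of the best fitness (default 20; Inf disables).
#' @param tournament Tournament size for parent selection.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param ncomp_choices Candidate values of the parametric gene (PLS
#'   component count).
#' @param k Folds of the fitness CV.
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(m_start = 5L, m_end = 20L, p_m = 0.05, pop = 50L,
                      generations = 100L, stagnation = 20L,
                      tournament = 3L, elitism = 1L,
                      ncomp_choices = 1:8, k = 10L, seed = 1L) {
  stopifnot(m_start >= 1L, m_start <= m_end, p_m > 0, p_m < 1, pop >= 2L,
            generations >= 1L, tournament >= 1L, elitism >= 0L, k >= 2L)
  structure(list(m_start = as.integer(m_start), m_end = as.integer(m_end),
                 p_m = p_m, pop = as.integer(pop),
                 generations = as.integer(generations),
                 stagnation = stagnation, tournament = as.integer(tournament),
                 elitism = as.integer(elitism),
                 ncomp_choices = as.integer(ncomp_choices),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "ga_config")
}

# clamp the number of selected genes into [m_start, m_end] by flipping
# random bits toward the nearer bound
.repair_mask <- function(mask, m_start, m_end) {
  m <- sum(mask)
  if (m > m_end) {
    drop <- sample(which(mask), m - m_end)
    mask[drop] <- FALSE
  } else if (m < m_start) {
    add <- sample(which(!mask), m_start - m)
    mask[add] <- TRUE
  }
  mask
}

#' Cross-validated MCC of a feature mask under the PLS meta evaluator
#'
#' Stratified k-fold CV of a PLS classifier restricted to the masked
#' columns, scored by pooled MCC.  Folds with a degenerate fit score
#' through the usual zero-denominator rules.
#'
#' @param X Feature (or PFV) matrix.
#' @param y Binary labels.
#' @param mask Logical or index column selector (non-empty).
#' @param ncomp PLS components (capped at the mask size).
#' @param k Folds.
#' @param seed Fold seed; pass `folds` instead to reuse a partition.
#' @param folds Optional precomputed fold vector (overrides seed).
#' @return CV MCC in [-1, 1].
#' @export
evaluate_mask <- function(X, y, mask, ncomp = 2L, k = 10L, seed = 1L,
                          folds = NULL) {
  X <- as.matrix(X)
  y01 <- .as_y01(y)
  if (is.numeric(mask)) mask <- seq_len(ncol(X)) %in% mask
  if (!any(mask)) stop("empty mask")
  Xs <- X[, mask, drop = FALSE]
  nc <- min(as.integer(ncomp), ncol(Xs))
  if (is.null(folds)) folds <- make_folds(y01, k, seed)
  oof <- rep(NA_real_, length(y01))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- pls1_fit(Xs[tr, , drop = FALSE], y01[tr], nc)
    oof[!tr] <- .pls_confidence(fit, Xs[!tr, , drop = FALSE])
  }
  score(y01, oof, protocol = "tuning")$MCC
}

# (fitness, m, mask-string) ordering: higher fitness, then fewer
# selected features, then lexicographically smaller mask
.better_than <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$fitness != b$fitness) return(a$fitness > b$fitness)
  if (a$m != b$m) return(a$m < b$m)
  a$key < b$key
}

.chrom_key <- function(mask) paste(as.integer(mask), collapse = "")

#' Genetic-algorithm feature selection maximising CV MCC
#'
#' Binary-mask chromosomes with a parametric PLS-component gene evolve
#' by tournament selection, uniform crossover, per-gene mutation and
#' count repair; fitness is the stratified k-fold CV MCC of the PLS
#' evaluator on the masked columns (one shared fold partition per run;
#' fitness values are cached by chromosome).  Elitism makes the
#' all-time best fitness non-decreasing across generations.
#'
#' @param X Feature or PFV matrix (n features >= `m_start`).
#' @param y Binary labels.
#' @param config A [ga_config()].
#' @param evaluator Fitness callback `function(mask, ncomp)` returning
#'   a CV MCC; the default wraps [evaluate_mask()] on `X`, `y`.
#' @return A `ga_result`: `best` (mask, ncomp, fitness, m), `history`
#'   (per-generation all-time-best fitness), `evaluations` (distinct
#'   chromosomes scored) and `config`.
#' @export
select_features <- function(X, y, config = ga_config(),
                            evaluator = NULL) {
  X <- as.matrix(X)
  y01 <- .as_y01(y)
  n <- ncol(X)
  if (n < config$m_start)
    stop("feature count ", n, " below m_start ", config$m_start)
  if (length(unique(y01)) < 2L) stop("y must contain both classes")
  m_end <- min(config$m_end, n)

  folds <- make_folds(y01, config$k, config$seed)
  if (is.null(evaluator)) {
    evaluator <- function(mask, ncomp)
      evaluate_mask(X, y01, mask, ncomp = ncomp, folds = folds)
  }
  cache <- new.env(parent = emptyenv())
  evaluate <- function(chrom) {
    key <- paste0(.chrom_key(chrom$mask), ":", chrom$ncomp)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- evaluator(chrom$mask, chrom$ncomp)
    if (!is.finite(fit)) stop("evaluator returned non-finite fitness for m=",
                              sum(chrom$mask))
    cache[[key]] <- fit
    fit
  }

  run <- function() {
    new_chrom <- function(mask, ncomp) {
      mask <- .repair_mask(mask, config$m_start, m_end)
      ch <- list(mask = mask, ncomp = ncomp, m = sum(mask),
                 key = .chrom_key(mask))
      ch$fitness <- evaluate(ch)
      ch
    }
    # init: uniform-random selected count in [m_start, m_end]
    pop <- lapply(seq_len(config$pop), function(i) {
      m <- sample(config$m_start:m_end, 1L)
      mask <- logical(n)
      mask[sample(n, m)] <- TRUE
      new_chrom(mask, sample(config$ncomp_choices, 1L))
    })
    best <- NULL
    for (ch in pop) if (.better_than(ch, best)) best <- ch
    history <- numeric(0)
    stale <- 0L
    for (g in seq_len(config$generations)) {
      fitnesses <- vapply(pop, `[[`, numeric(1), "fitness")
      tourney <- function() {
        idx <- sample(config$pop, config$tournament, replace = TRUE)
        pop[[idx[which.max(fitnesses[idx])]]]
      }
      elite <- pop[order(-fitnesses)][seq_len(config$elitism)]
      children <- vector("list", config$pop - config$elitism)
      for (i in seq_along(children)) {
        pa <- tourney(); pb <- tourney()
        take_a <- runif(n) < 0.5                     # uniform crossover
        mask <- ifelse(take_a, pa$mask, pb$mask)
        flip <- runif(n) < config$p_m                # per-gene mutation
        mask <- xor(mask, flip)
        ncomp <- if (runif(1) < 0.5) pa$ncomp else pb$ncomp
        if (runif(1) < config$p_m)
          ncomp <- sample(config$ncomp_choices, 1L)
        children[[i]] <- new_chrom(mask, ncomp)
      }
      pop <- c(elite, children)
      improved <- FALSE
      for (ch in pop) if (.better_than(ch, best)) { best <- ch; improved <- TRUE }
      history <- c(history, best$fitness)
      stale <- if (improved) 0L else stale + 1L
      if (stale >= config$stagnation) break
    }
    list(best = best, history = history)
  }
  res <- .with_seed(config$seed, run())
  structure(list(best = res$best[c("mask", "ncomp", "fitness", "m")],
                 history = res$history,
                 evaluations = length(ls(cache)),
                 columns = colnames(X)[res$best$mask],
                 config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("ga_result: ", x$best$m, " features selected (fitness ",
      sprintf("%.3f", x$best$fitness), ", ", x$best$ncomp,
      " PLS component(s), ", length(x$history), " generations, ",
      x$evaluations, " evaluations)\n", sep = "")
  if (!is.null(x$columns))
    cat("  columns: ", paste(x$columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}
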