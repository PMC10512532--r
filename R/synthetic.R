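# Synthetic data generators: a labelled peptide task with controllable
# compositional class signal, and a planted-signal PFV-like matrix for
# exercising the feature selector.

#' Default residue enrichment map of the synthetic positive class
#'
#' Frequency multipliers applied to the uniform residue distribution in
#' the positive class: Cys, Tyr, Arg, Phe strongly boosted, Trp and Met
#' moderately, Asp, Leu, Pro depleted — the compositional structure
#' reported for tyrosinase-inhibitory versus inactive peptides.
#' @return Named numeric multiplier vector over the 20 residues.
#' @export
synth_enrichment <- function() {
  mult <- setNames(rep(1, 20L), aa_alphabet())
  mult[c("C", "Y", "R", "F")] <- 3
  mult[c("W", "M")] <- 2
  mult[c("D", "L", "P")] <- 0.3
  mult
}

#' Generate a labelled synthetic peptide dataset
#'
#' Residues are drawn i.i.d. per sequence: the negative class from the
#' uniform distribution over the 20 residues, the positive class from
#' the uniform distribution blended at strength `s` with the
#' (renormalised) enrichment map — `s = 0` makes the classes
#' indistinguishable, `s = 1` applies the full compositional shift.
#' Lengths are uniform in `length_range`.  With `markov_order = TRUE`
#' the positive class additionally repeats its previous residue with
#' probability 0.3, giving dipeptide-level order signal for DPC/DDE.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Integer length bounds (min >= 2 so dipeptide
#'   encoders are always applicable).
#' @param s Signal strength in [0, 1].
#' @param enrichment Multiplier map, default [synth_enrichment()].
#' @param markov_order Add first-order repeat structure to positives.
#' @param seed Integer seed.
#' @return A labelled `peptide_set` (ids pos1.., neg1..).
#' @export
synth_peptides <- function(n_pos = 150L, n_neg = 150L,
                           length_range = c(5L, 25L), s = 1,
                           enrichment = synth_enrichment(),
                           markov_order = FALSE, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length_range[1] >= 2L,
            length_range[1] <= length_range[2], s >= 0, s <= 1)
  aa <- aa_alphabet()
  unif <- setNames(rep(1 / 20, 20L), aa)
  enriched <- enrichment[aa] / sum(enrichment[aa])
  p_pos <- (1 - s) * unif + s * enriched
  draw <- function(n, prob, repeat_p) {
    vapply(seq_len(n), function(i) {
      L <- sample(length_range[1]:length_range[2], 1L)
      ch <- sample(aa, L, replace = TRUE, prob = prob)
      if (repeat_p > 0 && L > 1L)
        for (j in 2:L) if (runif(1) < repeat_p) ch[j] <- ch[j - 1L]
      paste(ch, collapse = "")
    }, character(1))
  }
  .with_seed(seed, {
    pos <- draw(n_pos, p_pos, if (markov_order) 0.3 else 0)
    neg <- draw(n_neg, unif, 0)
    peptide_set(c(paste0("pos", seq_len(n_pos)),
                  paste0("neg", seq_len(n_neg))),
                c(pos, neg),
                label = rep(c("positive", "negative"), c(n_pos, n_neg)),
                name = sprintf("synthetic_s%g", s))
  })
}

#' Generate a planted-signal PFV-like matrix
#'
#' Noise columns are uniform pseudo-confidences on [0, 1]; the
#' `n_informative` planted columns are shifted by `+shift` for
#' positives and `-shift` for negatives, then clipped to [0, 1].
#'
#' @param n_samples Number of rows (balanced classes).
#' @param n_features Total columns (default 130).
#' @param n_informative Number of planted columns.
#' @param shift Mean shift applied toward the label.
#' @param seed Integer seed.
#' @return List with `X` (matrix, columns PF001..), `y` (0/1 labels)
#'   and `informative` (planted column indices).
#' @export
synth_planted_pfv <- function(n_samples = 200L, n_features = 130L,
                              n_informative = 5L, shift = 0.3,
                              seed = 1L) {
  stopifnot(n_informative >= 0L, n_informative <= n_features,
            n_samples >= 2L)
  .with_seed(seed, {
    y <- rep_len(c(1L, 0L), n_samples)
    X <- matrix(runif(n_samples * n_features), n_samples, n_features)
    informative <- if (n_informative > 0L)
      sort(sample(n_features, n_informative)) else integer(0)
    for (j in informative)
      X[, j] <- pmin(pmax(X[, j] + shift * (2 * y - 1), 0), 1)
    colnames(X) <- sprintf("PF%03d", seq_len(n_features))
    list(X = X, y = y, informative = informative)
  })
}
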