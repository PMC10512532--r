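# Sequence-based descriptors: AAC, DPC, DDE, PAAC, APAAC, PCP.
# Every encoder returns a named numeric vector of fixed length for one
# peptide; encode_features() stacks a whole dataset row-wise.

.dipeptide_names <- function() {
  aa <- aa_alphabet()
  as.vector(t(outer(aa, aa, paste0)))
}

.residue_counts <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = aa_alphabet()))
  as.numeric(tab)
}

.check_peptide <- function(sequence, min_len = 1L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  if (!.valid_sequence(sequence))
    stop("invalid residues: ", .offending_chars(sequence))
  if (nchar(sequence) < min_len)
    stop("sequence length ", nchar(sequence), " below minimum ", min_len)
  sequence
}

#' Amino acid composition (AAC, 20-D)
#'
#' Frequency of each of the 20 residues: count / length.  Components are
#' non-negative and sum to 1.
#' @param sequence A peptide sequence string.
#' @return Named numeric vector of length 20 (alphabetical order).
#' @export
encode_aac <- function(sequence) {
  sequence <- .check_peptide(sequence)
  setNames(.residue_counts(sequence) / nchar(sequence), aa_alphabet())
}

#' Dipeptide composition (DPC, 400-D)
#'
#' Frequency of each of the 400 ordered dipeptides among the L-1
#' overlapping pairs.
#' @inheritParams encode_aac
#' @return Named numeric vector of length 400 (AA, AC, ..., YY).
#' @export
encode_dpc <- function(sequence) {
  sequence <- .check_peptide(sequence, min_len = 2L)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  dip <- paste0(ch[-length(ch)], ch[-1])
  tab <- table(factor(dip, levels = .dipeptide_names()))
  setNames(as.numeric(tab) / (nchar(sequence) - 1L), .dipeptide_names())
}

#' Dipeptide deviation from expected mean (DDE, 400-D)
#'
#' For each dipeptide ab the observed composition DC = count/(L-1) is
#' standardised against its codon-usage expectation:
#' TM = (Ca/61)(Cb/61), TV = TM(1-TM)/(L-1), DDE = (DC-TM)/sqrt(TV),
#' with Ca the number of sense codons of residue a.
#' @inheritParams encode_aac
#' @param codons Codon count table, by default [codon_counts()].
#' @return Named numeric vector of length 400.
#' @export
encode_dde <- function(sequence, codons = codon_counts()) {
  sequence <- .check_peptide(sequence, min_len = 2L)
  dc <- encode_dpc(sequence)
  aa <- aa_alphabet()
  frac <- codons[aa] / sum(codons)
  tm <- as.vector(t(outer(frac, frac)))        # nested alphabetical order
  tv <- tm * (1 - tm) / (nchar(sequence) - 1L)
  setNames((dc - tm) / sqrt(tv), .dipeptide_names())
}

#' Pseudo amino acid composition (PAAC, (20+lambda)-D)
#'
#' Classic pseudo amino acid composition: the 20 residue frequencies
#' extended with lambda sequence-order correlation factors
#' theta_j = mean_i Theta(R_i, R_{i+j}), where Theta(x, y) is the mean
#' squared difference of three z-normalised scales (hydrophobicity,
#' hydrophilicity, side-chain mass) between the two residues.  The first
#' 20 components are f_a / (sum f + w sum theta), the last lambda are
#' w theta_j / (same denominator); all components sum to 1.
#'
#' @inheritParams encode_aac
#' @param lambda Sequence-order rank (default 1, matching a 21-D PAAC);
#'   0 reduces the encoder to AAC.  Requires L >= lambda + 1.
#' @param w Weight of the sequence-order terms (default 0.05).
#' @param scales 20 x 3 normalised scale matrix, see [paac_scales()].
#' @return Named numeric vector of length 20 + lambda.
#' @export
encode_paac <- function(sequence, lambda = 1L, w = 0.05,
                        scales = paac_scales()) {
  sequence <- .check_peptide(sequence, min_len = lambda + 1L)
  stopifnot(lambda >= 0L, w > 0)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(ch)
  f <- .residue_counts(sequence)               # raw counts / L cancels below
  f <- f / L
  theta <- numeric(lambda)
  if (lambda > 0L) {
    sc <- scales[ch, , drop = FALSE]
    for (j in seq_len(lambda)) {
      d <- sc[(1 + j):L, , drop = FALSE] - sc[1:(L - j), , drop = FALSE]
      theta[j] <- mean(rowMeans(d^2))
    }
  }
  denom <- sum(f) + w * sum(theta)
  out <- c(f, w * theta) / denom
  names(out) <- c(aa_alphabet(),
                  if (lambda > 0L) paste0("lambda", seq_len(lambda)))
  out
}

#' Amphiphilic pseudo amino acid composition (APAAC, (20+2*lambda)-D)
#'
#' Like PAAC but with 2*lambda amphiphilic correlation factors:
#' tau_{2j-1} = mean_i H1(R_i) H1(R_{i+j}) and tau_{2j} the same product
#' on the hydrophilicity scale H2.  Components sum to 1; tau terms can
#' be negative because the scales are zero-mean.
#'
#' @inheritParams encode_paac
#' @return Named numeric vector of length 20 + 2*lambda.
#' @export
encode_apaac <- function(sequence, lambda = 1L, w = 0.05,
                         scales = paac_scales()) {
  sequence <- .check_peptide(sequence, min_len = lambda + 1L)
  stopifnot(lambda >= 0L, w > 0)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(ch)
  f <- .residue_counts(sequence) / L
  tau <- numeric(2L * lambda)
  if (lambda > 0L) {
    h1 <- scales[ch, 1]; h2 <- scales[ch, 2]
    for (j in seq_len(lambda)) {
      i1 <- 1:(L - j); i2 <- (1 + j):L
      tau[2L * j - 1L] <- mean(h1[i1] * h1[i2])
      tau[2L * j]      <- mean(h2[i1] * h2[i2])
    }
  }
  denom <- sum(f) + w * sum(tau)
  out <- c(f, w * tau) / denom
  names(out) <- c(aa_alphabet(),
                  if (lambda > 0L)
                    paste0("tau", seq_len(2L * lambda)))
  out
}

#' Physicochemical property means (PCP, 11-D by default)
#'
#' Component k is the mean of property scale k over the residues of the
#' sequence; order-invariant by construction.
#' @inheritParams encode_aac
#' @param props 20 x k property matrix, see [pcp_scales()].
#' @return Named numeric vector, one component per scale.
#' @export
encode_pcp <- function(sequence, props = pcp_scales()) {
  sequence <- .check_peptide(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  colMeans(props[ch, , drop = FALSE])
}
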