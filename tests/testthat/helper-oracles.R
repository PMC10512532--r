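# Independent oracles used to cross-check the encoders and metrics.
# These deliberately re-derive every quantity step by step from the
# published formulas, sharing nothing with the package implementations
# beyond the residue tables they are defined over.

random_peptide <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# DDE: DC, TM, TV computed literally per dipeptide
oracle_dde <- function(seq) {
  aa <- aa_alphabet()
  codons <- codon_counts()
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  out <- numeric(0)
  for (a in aa) for (b in aa) {
    dc <- 0
    for (i in seq_len(L - 1))
      if (ch[i] == a && ch[i + 1] == b) dc <- dc + 1
    dc <- dc / (L - 1)
    tm <- (codons[[a]] / 61) * (codons[[b]] / 61)
    tv <- tm * (1 - tm) / (L - 1)
    out <- c(out, (dc - tm) / sqrt(tv))
  }
  setNames(out, as.vector(t(outer(aa, aa, paste0))))
}

# PAAC: Theta as mean squared scale difference, explicit loops
oracle_paac <- function(seq, lambda = 1, w = 0.05) {
  sc <- paac_scales()
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  Theta <- function(x, y) mean((sc[y, ] - sc[x, ])^2)
  theta <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(L - j)) acc <- acc + Theta(ch[i], ch[i + j])
    theta[j] <- acc / (L - j)
  }
  f <- vapply(aa_alphabet(), function(a) sum(ch == a) / L, numeric(1))
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# APAAC: per-scale products of H1 / H2
oracle_apaac <- function(seq, lambda = 1, w = 0.05) {
  sc <- paac_scales()
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  tau <- numeric(2 * lambda)
  for (j in seq_len(lambda)) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(L - j)) {
      s1 <- s1 + sc[ch[i], 1] * sc[ch[i + j], 1]
      s2 <- s2 + sc[ch[i], 2] * sc[ch[i + j], 2]
    }
    tau[2 * j - 1] <- s1 / (L - j)
    tau[2 * j] <- s2 / (L - j)
  }
  f <- vapply(aa_alphabet(), function(a) sum(ch == a) / L, numeric(1))
  denom <- sum(f) + w * sum(tau)
  c(f / denom, w * tau / denom)
}

# AUC by brute-force pair counting (ties count half)
oracle_auc <- function(y01, conf) {
  pos <- conf[y01 == 1]; neg <- conf[y01 == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# small labelled dataset used across tests
tiny_labeled_set <- function(n_pos = 20, n_neg = 20, seed = 42) {
  synth_peptides(n_pos, n_neg, length_range = c(5, 15), s = 1, seed = seed)
}
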