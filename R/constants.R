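# Residue-level reference tables shared by the encoders and the SMILES
# builder.  Scales that a user may want to swap (PAAC triple, PCP table)
# live in inst/extdata as TSV; invariant chemistry (codon counts,
# elemental formulas, SMILES templates) is fixed here.

#' The 20-letter standard amino-acid alphabet, alphabetical order
#'
#' All feature columns are named in this order (dipeptides in the nested
#' alphabetical double loop AA, AC, ..., YY).
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Standard genetic code codon counts per residue
#'
#' Number of sense codons encoding each residue (61 in total, stop
#' codons excluded).  Used by the DDE encoder's theoretical dipeptide
#' means.
#' @return Named integer vector over the 20 residues.
#' @export
codon_counts <- function() {
  c(A = 4L, C = 2L, D = 2L, E = 2L, F = 2L, G = 4L, H = 2L, I = 3L,
    K = 2L, L = 6L, M = 1L, N = 2L, P = 4L, Q = 2L, R = 6L, S = 6L,
    T = 4L, V = 4L, W = 1L, Y = 2L)
}

# elemental average atomic weights consistent with a water mass of
# 18.01528 Da (H2O = 2*1.00794 + 15.9994)
.atomic_weights <- c(H = 1.00794, C = 12.0107, N = 14.0067,
                     O = 15.9994, S = 32.065)

# elemental composition of the free amino acids (C, H, N, O, S)
.aa_formulas <- list(
  A = c(3, 7, 1, 2, 0),  C = c(3, 7, 1, 2, 1),  D = c(4, 7, 1, 4, 0),
  E = c(5, 9, 1, 4, 0),  F = c(9, 11, 1, 2, 0), G = c(2, 5, 1, 2, 0),
  H = c(6, 9, 3, 2, 0),  I = c(6, 13, 1, 2, 0), K = c(6, 14, 2, 2, 0),
  L = c(6, 13, 1, 2, 0), M = c(5, 11, 1, 2, 1), N = c(4, 8, 2, 3, 0),
  P = c(5, 9, 1, 2, 0),  Q = c(5, 10, 2, 3, 0), R = c(6, 14, 4, 2, 0),
  S = c(3, 7, 1, 3, 0),  T = c(4, 9, 1, 3, 0),  V = c(5, 11, 1, 2, 0),
  W = c(11, 12, 2, 2, 0), Y = c(9, 11, 1, 3, 0))

#' Average molecular masses of the free amino acids
#'
#' Computed from elemental formulas with atomic weights chosen so that
#' water weighs exactly 18.01528 Da, making the peptide mass balance
#' `sum(residues) - (L-1) * 18.01528` exact for the SMILES builder.
#' @return Named numeric vector (Da) over the 20 residues.
#' @export
aa_masses <- function() {
  w <- .atomic_weights[c("C", "H", "N", "O", "S")]
  vapply(.aa_formulas, function(f) sum(f * w), numeric(1))
}

#' Mass of one water molecule (Da)
#' @return Numeric scalar, 18.01528.
#' @export
water_mass <- function() 18.01528

# per-residue SMILES fragments, N-to-C; fragment i's carbonyl carbon
# bonds to fragment i+1's leading nitrogen, the chain ends with "O".
# All alpha carbons carry the L configuration ([C@@H] written N-first);
# Ile and Thr carry their beta stereocentre too.
.aa_smiles_l <- c(
  A = "N[C@@H](C)C(=O)",
  C = "N[C@@H](CS)C(=O)",
  D = "N[C@@H](CC(O)=O)C(=O)",
  E = "N[C@@H](CCC(O)=O)C(=O)",
  F = "N[C@@H](Cc1ccccc1)C(=O)",
  G = "NCC(=O)",
  H = "N[C@@H](Cc1c[nH]cn1)C(=O)",
  I = "N[C@@H]([C@@H](C)CC)C(=O)",
  K = "N[C@@H](CCCCN)C(=O)",
  L = "N[C@@H](CC(C)C)C(=O)",
  M = "N[C@@H](CCSC)C(=O)",
  N = "N[C@@H](CC(N)=O)C(=O)",
  P = "N1CCC[C@H]1C(=O)",
  Q = "N[C@@H](CCC(N)=O)C(=O)",
  R = "N[C@@H](CCCNC(=N)N)C(=O)",
  S = "N[C@@H](CO)C(=O)",
  T = "N[C@@H]([C@H](O)C)C(=O)",
  V = "N[C@@H](C(C)C)C(=O)",
  W = "N[C@@H](Cc1c[nH]c2ccccc12)C(=O)",
  Y = "N[C@@H](Cc1ccc(O)cc1)C(=O)")

# achiral variants (stereo stripped)
.aa_smiles_flat <- gsub("\\[C@@?H\\]", "C", .aa_smiles_l)

.read_scale_table <- function(file) {
  path <- system.file("extdata", file, package = "pepstack")
  if (!nzchar(path)) stop("shipped scale table not found: ", file)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(identical(sort(tab$residue), aa_alphabet()))
  rownames(tab) <- tab$residue
  as.matrix(tab[aa_alphabet(), setdiff(names(tab), "residue"), drop = FALSE])
}

#' Physicochemical scale triple used by PAAC/APAAC
#'
#' Hydrophobicity, hydrophilicity and side-chain mass per residue,
#' z-score normalised over the 20 residues (population standard
#' deviation, the convention of the pseudo amino acid composition
#' descriptor family).  Raw values are shipped in
#' `extdata/paac_scales.tsv` and can be replaced via `file`.
#'
#' @param file Optional path to a TSV with columns residue,
#'   hydrophobicity, hydrophilicity, sidechain_mass.
#' @return 20 x 3 numeric matrix, rows in alphabetical residue order.
#' @export
paac_scales <- function(file = NULL) {
  if (is.null(file)) {
    if (is.null(.pepstack_cache$paac)) {
      .pepstack_cache$paac <- .normalize_scales(.read_scale_table("paac_scales.tsv"))
    }
    return(.pepstack_cache$paac)
  }
  tab <- read.delim(file, stringsAsFactors = FALSE)
  rownames(tab) <- tab$residue
  .normalize_scales(as.matrix(tab[aa_alphabet(), setdiff(names(tab), "residue")]))
}

# zero mean, unit population sd per column over the 20 residues
.normalize_scales <- function(m) {
  apply(m, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
}

#' Default 11-scale physicochemical property table for the PCP encoder
#'
#' Eleven per-residue scales (hydrophobicity, hydrophilicity, side-chain
#' mass, volume, polarity, polarizability, isoelectric point, net charge
#' index, helix propensity, sheet propensity, flexibility), shipped in
#' `extdata/pcp_scales.tsv`; any TSV with a `residue` column plus one
#' column per scale can be substituted.
#'
#' @param file Optional path to a user property TSV.
#' @return 20 x k numeric matrix (k = 11 for the default).
#' @export
pcp_scales <- function(file = NULL) {
  if (is.null(file)) {
    if (is.null(.pepstack_cache$pcp)) {
      .pepstack_cache$pcp <- .read_scale_table("pcp_scales.tsv")
    }
    return(.pepstack_cache$pcp)
  }
  tab <- read.delim(file, stringsAsFactors = FALSE)
  rownames(tab) <- tab$residue
  as.matrix(tab[aa_alphabet(), setdiff(names(tab), "residue")])
}
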