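# Peptide -> SMILES conversion.  Linear peptides are assembled from
# per-residue fragments "N[C@@H](side)C(=O)" joined head-to-tail by the
# amide bond, with a free N-terminal amine and free C-terminal
# carboxylic acid.  Residues are emitted as L-amino acids (Ile and Thr
# with their beta stereocentre); `stereo = FALSE` strips stereo for the
# substructure-key use case, where the four fingerprint families are
# insensitive to it.

#' Convert peptide sequences to SMILES
#'
#' @param x A `peptide_set` or character vector of sequences.
#' @param stereo Emit L-configuration stereocentres (default TRUE).
#' @return Character vector of SMILES strings (named by id when `x` is
#'   a `peptide_set`).
#' @export
peptide_to_smiles <- function(x, stereo = TRUE) {
  seqs <- if (inherits(x, "peptide_set")) x$sequence else toupper(x)
  tmpl <- if (stereo) .aa_smiles_l else .aa_smiles_flat
  out <- vapply(seqs, function(s) {
    s <- .check_peptide(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste0(paste(tmpl[ch], collapse = ""), "O")
  }, character(1), USE.NAMES = FALSE)
  if (inherits(x, "peptide_set")) names(out) <- x$id
  out
}

#' Expected average molecular weight of a linear peptide
#'
#' Mass balance: sum of free amino-acid masses minus (L-1) waters lost
#' to amide-bond formation.
#' @param sequence Peptide sequence string.
#' @return Average molecular weight in Da.
#' @export
peptide_mw <- function(sequence) {
  sequence <- .check_peptide(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  sum(aa_masses()[ch]) - (length(ch) - 1L) * water_mass()
}

# parse SMILES into OpenBabel molecule handles (one per string)
.parse_smiles <- function(smiles) {
  mols <- lapply(smiles, function(s)
    ChemmineOB::forEachMol("SMILES", s, identity))
  bad <- vapply(mols, function(m) length(m) == 0L, logical(1))
  if (any(bad)) stop("unparseable SMILES: ",
                     paste(head(smiles[bad], 3L), collapse = "; "))
  mols
}

#' Molecular properties of SMILES via the OpenBabel backend
#'
#' @param smiles Character vector of SMILES.
#' @return data.frame with columns smiles, formula, mw (average
#'   molecular weight, Da).
#' @export
smiles_properties <- function(smiles) {
  props <- lapply(.parse_smiles(smiles), ChemmineOB::prop_OB)
  data.frame(smiles = smiles,
             formula = vapply(props, function(p) p$formula, character(1)),
             mw = vapply(props, function(p) p$MW, numeric(1)),
             stringsAsFactors = FALSE)
}
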