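# Keyed substructure fingerprints (Estate 79, FP4 307, MACCS 166,
# PubChem 881).  Each family is a dictionary of (SMARTS, minimum match
# count) keys; bit k is 1 iff pattern k matches the molecule at least
# min_count times.  The reference key definitions of these families are
# third-party data files that cannot be redistributed here, so the
# dictionaries below are SYNTHETIC key sets: generated in code, at the
# exact published dimensions, from (a) a head of genuine named
# functional-group SMARTS and (b) systematic atom-type / element-count /
# bonded-path patterns.  Bit semantics (presence/absence of a named
# substructure) and dimensions match the reference families; individual
# bit definitions do not.  Matching runs on the OpenBabel SMARTS engine
# via ChemmineOB.

# genuine functional-group SMARTS, used as the head of FP4 and MACCS so
# chemically meaningful groups (amine, carboxylic acid, thiol, ...) own
# the first bits
.fg_smarts <- function() {
  c(amine_primary      = "[NX3;H2;!$(NC=O)]",
    amine_secondary    = "[NX3;H1;!$(NC=O)]([#6])[#6]",
    amine_tertiary     = "[NX3;H0;!$(NC=O)]([#6])([#6])[#6]",
    ammonium           = "[NX4+]",
    amide              = "[NX3][CX3](=[OX1])",
    amide_Nsub         = "[NX3;H1][CX3](=[OX1])[#6]",
    carboxylic_acid    = "[CX3](=[OX1])[OX2H1]",
    carboxylate        = "[CX3](=[OX1])[OX1-]",
    ester              = "[CX3](=[OX1])[OX2][#6]",
    ketone             = "[#6][CX3](=[OX1])[#6]",
    aldehyde           = "[CX3H1](=[OX1])",
    alcohol            = "[CX4][OX2H]",
    phenol             = "[c][OX2H]",
    ether              = "[#6][OX2;H0][#6]",
    thiol              = "[SX2H]",
    thioether          = "[#6][SX2;H0][#6]",
    disulfide          = "[SX2][SX2]",
    guanidine          = "[NX3][CX3](=[NX2,NX3+])[NX3]",
    imidazole          = "c1c[nH]cn1",
    indole             = "c1cc2c(cc1)[nH]cc2",
    phenyl             = "c1ccccc1",
    aromatic_N         = "[n]",
    aromatic_NH        = "[nH]",
    hydroxyl_any       = "[OX2H]",
    carbonyl           = "[CX3]=[OX1]",
    nitrile            = "[NX1]#[CX2]",
    nitro              = "[NX3](=O)=O",
    sulfoxide          = "[SX3]=[OX1]",
    sulfone            = "[SX4](=[OX1])=[OX1]",
    sulfonamide        = "[SX4](=[OX1])(=[OX1])[NX3]",
    phosphate          = "[PX4](=[OX1])",
    alkene             = "[CX3]=[CX3]",
    alkyne             = "[CX2]#[CX2]",
    halide_F           = "[F]",
    halide_Cl          = "[Cl]",
    halide_Br          = "[Br]",
    halide_I           = "[I]",
    methyl             = "[CH3]",
    methylene_chain    = "[CH2][CH2]",
    isopropyl          = "[CH3][CH1]([CH3])",
    alpha_amino_acid   = "[NX3][CX4][CX3](=[OX1])[OX2H1]",
    peptide_bond       = "[CX3](=[OX1])[NX3][CX4]",
    imine              = "[CX3]=[NX2]",
    hydroxymethyl      = "[OX2H][CH2]",
    benzyl             = "[CH2]c1ccccc1",
    ring_any           = "[R]",
    ring_fused_atom    = "[R2]",
    heteroaromatic5    = "[a;r5]",
    heteroaromatic6    = "[a;r6]",
    carbamoyl          = "[CX3](=[OX1])[NX3;H2]")
}

# systematic pattern pools --------------------------------------------

# atom types: element x valence context x H count (some combinations
# can never match real molecules; their bits are constitutively 0,
# which keyed dictionaries tolerate)
.pool_atom_types <- function() {
  base <- c("CX4", "CX3", "CX2", "c",
            "NX3", "NX2", "NX1", "n", "NX4+",
            "OX2", "OX1", "o",
            "SX2", "SX1", "s", "SX4",
            "PX3", "PX4")
  out <- character(0)
  for (b in base) {
    hmax <- if (grepl("^[cnos]", b)) 1L else 3L
    charged <- grepl("\\+$", b)
    core <- sub("\\+$", "", b)
    for (h in 0:hmax)
      out <- c(out, paste0("[", core, "H", h, if (charged) "+", "]"))
  }
  c(out, "[F]", "[Cl]", "[Br]", "[I]")
}

# ring-context atom types
.pool_ring_types <- function() {
  base <- c("CX4", "CX3", "NX3", "NX2", "OX2", "SX2", "c", "n")
  c(paste0("[", base, ";R]"), paste0("[r", 3:8, "]"))
}

# bonded element pairs with explicit bond orders
.pool_pairs <- function() {
  els <- c("#6", "#7", "#8", "#16", "#15")
  out <- character(0)
  for (i in seq_along(els)) for (j in i:length(els))
    for (b in c("-", "=", "~"))
      out <- c(out, paste0("[", els[i], "]", b, "[", els[j], "]"))
  ar <- c("c", "n", "o", "s")
  for (i in seq_along(ar)) for (j in i:length(ar))
    out <- c(out, paste0("[", ar[i], "]:[", ar[j], "]"))
  out
}

# element pairs separated by one or two wildcard atoms
.pool_paths <- function() {
  els <- c("#6", "#7", "#8", "#16")
  out <- character(0)
  for (gap in c("~*~", "~*~*~", "~*~*~*~"))
    for (i in seq_along(els)) for (j in i:length(els))
      out <- c(out, paste0("[", els[i], "]", gap, "[", els[j], "]"))
  out
}

# element triples a~b~c (centre b free, ends unordered)
.pool_triples <- function() {
  els <- c("#6", "#7", "#8", "#16")
  out <- character(0)
  for (b in els) for (i in seq_along(els)) for (j in i:length(els))
    out <- c(out, paste0("[", els[i], "]~[", b, "]~[", els[j], "]"))
  out
}

# four-atom chains over C/N/O, deduplicated up to reversal
.pool_chains4 <- function() {
  els <- c("#6", "#7", "#8")
  combos <- expand.grid(a = els, b = els, c = els, d = els,
                        stringsAsFactors = FALSE)
  key <- apply(combos, 1, function(r) {
    fwd <- paste(r, collapse = "|")
    rev <- paste(rev(r), collapse = "|")
    min(fwd, rev)
  })
  combos <- combos[!duplicated(key), ]
  apply(combos, 1, function(r)
    paste0("[", r[1], "]~[", r[2], "]~[", r[3], "]~[", r[4], "]"))
}

# five-atom chains over C/N/O, deduplicated up to reversal
.pool_chains5 <- function() {
  els <- c("#6", "#7", "#8")
  combos <- expand.grid(a = els, b = els, c = els, d = els, e = els,
                        stringsAsFactors = FALSE)
  key <- apply(combos, 1, function(r) {
    fwd <- paste(r, collapse = "|")
    rev <- paste(rev(r), collapse = "|")
    min(fwd, rev)
  })
  combos <- combos[!duplicated(key), ]
  apply(combos, 1, function(r)
    paste0("[", r[1], "]~[", r[2], "]~[", r[3], "]~[", r[4], "]~[",
           r[5], "]"))
}

# element triples with explicit bond orders on both edges
.pool_triples_bonded <- function() {
  els <- c("#6", "#7", "#8", "#16")
  out <- character(0)
  for (b in els) for (i in seq_along(els)) for (j in i:length(els))
    for (b1 in c("-", "=")) for (b2 in c("-", "=")) {
      if (i == j && b1 > b2) next   # symmetric ends: keep one bond order
      out <- c(out, paste0("[", els[i], "]", b1, "[", b, "]", b2,
                           "[", els[j], "]"))
    }
  out
}

# (smarts, min_count) rows for element/substructure count thresholds
.count_block <- function(smarts, thresholds) {
  do.call(rbind, lapply(seq_along(smarts), function(i)
    data.frame(smarts = smarts[i], min_count = thresholds,
               stringsAsFactors = FALSE)))
}

.take <- function(pool, n, family) {
  if (nrow(pool) < n)
    stop("internal: pattern pool for ", family, " has only ",
         nrow(pool), " entries, need ", n)
  out <- pool[seq_len(n), , drop = FALSE]
  out$name <- sprintf("%s%03d", family, seq_len(n))
  has_desc <- !is.na(out$desc) & nzchar(out$desc)
  out$name[has_desc] <- paste0(out$name[has_desc], "_", out$desc[has_desc])
  rownames(out) <- NULL
  out[, c("name", "smarts", "min_count")]
}

.presence <- function(smarts, desc = NA_character_) {
  data.frame(smarts = smarts, min_count = 1L, desc = desc,
             stringsAsFactors = FALSE)
}

#' Fingerprint family specifications
#'
#' The four keyed families and their fixed dimensions.
#' @return data.frame with columns name and dimension.
#' @export
fingerprint_specs <- function() {
  data.frame(name = c("Estate", "FP4", "MACCS", "PubChem"),
             dimension = c(79L, 307L, 166L, 881L),
             stringsAsFactors = FALSE)
}

#' Synthetic keyed pattern dictionary of a fingerprint family
#'
#' Returns the (SMARTS, minimum match count) key list that defines each
#' bit of the named family.  These are synthetic key sets generated in
#' code (see the file header of `R/fingerprints.R`): dimensions and bit
#' semantics follow the published families, the individual key
#' definitions do not.
#'
#' @param spec Family name: "Estate", "FP4", "MACCS" or "PubChem".
#' @return data.frame with columns name, smarts, min_count; exactly as
#'   many rows as the family's dimension.
#' @export
fingerprint_patterns <- function(spec) {
  spec <- match.arg(spec, fingerprint_specs()$name)
  key <- paste0("fp_", spec)
  if (!is.null(.pepstack_cache[[key]])) return(.pepstack_cache[[key]])
  dim <- fingerprint_specs()$dimension[fingerprint_specs()$name == spec]
  pool <- switch(spec,
    Estate = .presence(c(.pool_atom_types(), .pool_ring_types())),
    FP4 = {
      fg <- .fg_smarts()
      rbind(.presence(unname(fg), names(fg)),
            .presence(.pool_pairs()),
            .presence(.pool_triples()),
            .presence(.pool_chains4()),
            .presence(.pool_paths()),
            .presence(.pool_chains5()))
    },
    MACCS = {
      fg <- .fg_smarts()
      counts <- .count_block(
        c("[#6]", "[#7]", "[#8]", "[#16]", "[R]", "[c]", "[CH3]", "[OX2H]"),
        c(1L, 2L, 4L, 8L))
      counts$desc <- NA_character_
      rbind(.presence(unname(fg), names(fg)),
            counts,
            .presence(.pool_paths()),
            .presence(.pool_pairs()))
    },
    PubChem = {
      counts <- .count_block(
        c("[#6]", "[#7]", "[#8]", "[#16]", "[#15]", "[F,Cl,Br,I]",
          "[R]", "[a]", "[CH3]", "[CH2]", "[OX2H]", "[NX3]", "[CX3]=[OX1]"),
        c(1L, 2L, 4L, 8L, 16L, 32L))
      counts$desc <- NA_character_
      pairs2 <- .presence(.pool_pairs()); pairs2$min_count <- 2L
      paths2 <- .presence(.pool_paths()); paths2$min_count <- 2L
      triples2 <- .presence(.pool_triples()); triples2$min_count <- 2L
      chains2 <- .presence(.pool_chains4()); chains2$min_count <- 2L
      chains52 <- .presence(.pool_chains5()); chains52$min_count <- 2L
      fg <- .fg_smarts()
      rbind(counts,
            .presence(unname(fg), names(fg)),
            .presence(c(.pool_atom_types(), .pool_ring_types())),
            .presence(.pool_pairs()),
            .presence(.pool_triples()),
            .presence(.pool_triples_bonded()),
            .presence(.pool_chains4()),
            .presence(.pool_chains5()),
            .presence(.pool_paths()),
            pairs2, triples2, chains2, paths2, chains52)
    })
  if (is.null(pool$desc)) pool$desc <- NA_character_
  out <- .take(pool, dim, spec)
  .pepstack_cache[[key]] <- out
  out
}

#' Compute a keyed substructure fingerprint matrix
#'
#' @param x SMILES character vector, or a `peptide_set` (converted with
#'   [peptide_to_smiles()]).
#' @param spec Family name: "Estate", "FP4", "MACCS" or "PubChem".
#' @return Binary integer matrix, one row per molecule, one named
#'   column per key; dimension fixed by the family.
#' @export
encode_fingerprint <- function(x, spec) {
  pat <- fingerprint_patterns(spec)
  smiles <- if (inherits(x, "peptide_set")) peptide_to_smiles(x) else x
  mols <- .parse_smiles(smiles)
  usm <- unique(pat$smarts)
  counts <- matrix(0L, nrow = length(mols), ncol = length(usm),
                   dimnames = list(NULL, usm))
  for (s in usm) {
    counts[, s] <- vapply(mols, function(m)
      as.integer(ChemmineOB::smartsSearch_OB(m, s, uniqueMatches = TRUE)),
      integer(1))
  }
  bits <- matrix(0L, nrow = length(mols), ncol = nrow(pat),
                 dimnames = list(names(smiles), pat$name))
  for (k in seq_len(nrow(pat)))
    bits[, k] <- as.integer(counts[, pat$smarts[k]] >= pat$min_count[k])
  bits
}
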