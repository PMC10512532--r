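test_that("SMILES assembly produces the expected linear peptides", {
  expect_equal(unname(peptide_to_smiles("G", stereo = FALSE)), "NCC(=O)O")
  expect_equal(unname(peptide_to_smiles("GG", stereo = FALSE)),
               "NCC(=O)NCC(=O)O")
  # determinism
  expect_identical(peptide_to_smiles("ACDKW"), peptide_to_smiles("ACDKW"))
  # ids carried over from a peptide_set
  ds <- peptide_set(c("a", "b"), c("GG", "AC"))
  expect_named(peptide_to_smiles(ds), c("a", "b"))
})

test_that("molecular weight honours the residue mass balance", {
  # dipeptide closed form: 2 x glycine - one water
  props <- smiles_properties(peptide_to_smiles("GG"))
  expect_equal(props$mw, 2 * unname(aa_masses()["G"]) - water_mass(),
               tolerance = 0.01)
  set.seed(5)
  for (len in c(1, 2, 7, 18, 30)) {
    p <- random_peptide(len)
    mw <- smiles_properties(peptide_to_smiles(p))$mw
    expect_equal(mw, peptide_mw(p), tolerance = 0.01)
  }
})

test_that("fingerprints have fixed dimensions and binary values", {
  smi <- peptide_to_smiles(c("ACK", "GG"))
  specs <- fingerprint_specs()
  for (i in seq_len(nrow(specs))) {
    fp <- encode_fingerprint(smi, specs$name[i])
    expect_equal(ncol(fp), specs$dimension[i])
    expect_equal(nrow(fp), 2L)
    expect_true(all(fp %in% c(0L, 1L)))
  }
  expect_error(encode_fingerprint(smi, "Morgan"))
})

test_that("glycine FP4 bits reflect its functional groups", {
  fp <- encode_fingerprint("NCC(=O)O", "FP4")
  expect_equal(unname(fp[1, "FP4001_amine_primary"]), 1L)
  expect_equal(unname(fp[1, "FP4007_carboxylic_acid"]), 1L)
  expect_equal(unname(fp[1, "FP4015_thiol"]), 0L)
  # cysteine has the thiol
  fpc <- encode_fingerprint(peptide_to_smiles("C"), "FP4")
  expect_equal(unname(fpc[1, "FP4015_thiol"]), 1L)
})

test_that("fingerprints depend on the molecule, not the SMILES spelling", {
  # same molecule written two ways
  a <- encode_fingerprint("NCC(=O)O", "MACCS")
  b <- encode_fingerprint("OC(=O)CN", "MACCS")
  expect_equal(unname(a), unname(b))
  # identical sequences always give identical bits
  x <- encode_fingerprint(peptide_to_smiles("ACW"), "Estate")
  y <- encode_fingerprint(peptide_to_smiles("ACW"), "Estate")
  expect_identical(x, y)
})
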