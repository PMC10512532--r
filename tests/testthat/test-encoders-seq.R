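test_that("composition encoders match hand-computed values", {
  aac <- encode_aac("AAAA")
  expect_equal(unname(aac["A"]), 1)
  expect_equal(sum(aac), 1)
  expect_equal(unname(encode_aac("ACDE")[c("A", "C", "D", "E")]),
               rep(0.25, 4))

  dpc <- encode_dpc("AAAA")
  expect_equal(unname(dpc["AA"]), 1)
  dpc2 <- encode_dpc("ACAC")
  expect_equal(unname(dpc2[c("AC", "CA")]), c(2 / 3, 1 / 3))
  expect_error(encode_dpc("A"), "length")
  expect_error(encode_aac(""), "non-empty|empty")
})

test_that("DDE follows the codon-expectation formula exactly", {
  # two-residue closed form: DC(AA)=1, TM=(4/61)^2, TV=TM(1-TM)
  dde <- encode_dde("AA")
  tm <- (4 / 61)^2
  expect_equal(unname(dde["AA"]), (1 - tm) / sqrt(tm * (1 - tm)))
  # every absent dipeptide has DC=0 and hence a strictly negative score
  expect_true(all(dde[setdiff(names(dde), "AA")] < 0))
  # full agreement with the brute-force oracle
  set.seed(7)
  for (len in c(2, 3, 9, 30)) {
    p <- random_peptide(len)
    expect_equal(encode_dde(p), oracle_dde(p), tolerance = 1e-12)
  }
})

test_that("PAAC and APAAC match their step-by-step oracles and normalise", {
  # homopolymer: all scale differences vanish, so PAAC falls back to AAC
  p <- encode_paac("AAAA", lambda = 1)
  expect_equal(unname(p["lambda1"]), 0)
  expect_equal(p[1:20], encode_aac("AAAA"))

  expect_equal(unname(encode_paac("ACAC", lambda = 1, w = 0.05)),
               unname(oracle_paac("ACAC")), tolerance = 1e-12)

  ap <- encode_apaac("AAAA", lambda = 1)
  sc <- paac_scales()
  expect_equal(unname(ap["tau1"]) / (0.05 / (1 + 0.05 * (sc["A", 1]^2 + sc["A", 2]^2))),
               sc["A", 1]^2, tolerance = 1e-12)
  set.seed(13)
  for (len in c(4, 12, 25)) {
    q <- random_peptide(len)
    expect_equal(unname(encode_paac(q)), unname(oracle_paac(q)),
                 tolerance = 1e-12)
    expect_equal(unname(encode_apaac(q)), unname(oracle_apaac(q)),
                 tolerance = 1e-12)
    expect_equal(sum(encode_paac(q)), 1, tolerance = 1e-12)
    expect_equal(sum(encode_apaac(q)), 1, tolerance = 1e-12)
  }
  # lambda = 0 reduces both to plain composition
  expect_equal(unname(encode_paac("ACDKW", lambda = 0)),
               unname(encode_aac("ACDKW")))
  expect_equal(unname(encode_apaac("ACDKW", lambda = 0)),
               unname(encode_aac("ACDKW")))
  expect_error(encode_paac("AC", lambda = 2), "length")
})

test_that("PCP averages scales and ignores residue order", {
  pcp <- encode_pcp("GGGG")
  expect_equal(unname(pcp), unname(pcp_scales()["G", ]))
  expect_equal(encode_pcp("ACDE"), encode_pcp("EDCA"))
  expect_length(pcp, 11L)
})

test_that("dataset encoding equals per-peptide encoding, rows in order", {
  ds <- tiny_labeled_set(5, 5)
  m <- encode_features(ds, "PAAC")
  expect_equal(rownames(m), ds$id)
  for (i in c(1, 6)) {
    expect_equal(unname(m[i, ]), unname(encode_paac(ds$sequence[i])))
  }
  expect_identical(encode_features(ds, "AAC"), encode_features(ds, "AAC"))
})
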