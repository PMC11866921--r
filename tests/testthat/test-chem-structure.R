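# Parent and reference structures used throughout the suite.
parent_smiles <- c(
  FLE = "O=C(NCC1CCCCN1)c1cc(OCC(F)(F)F)ccc1OCC(F)(F)F",
  MET = "CC(C)NCC(O)COc1ccc(CCOC)cc1",
  SMX = "Cc1onc(NS(=O)(=O)c2ccc(N)cc2)c1",
  PHE = "CC1=CC(=O)N(c2ccccc2)N1C")

test_that("SMILES-derived formulas agree with the OpenBabel oracle", {
  smis <- c(parent_smiles,
            ANI = "Nc1ccccc1", SAA = "Nc1ccc(cc1)S(=O)(=O)O",
            AMI = "Cc1onc(N)c1", DIP = "NCC(O)COc1ccc(CCOC)cc1",
            CAF = "Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  sdf <- ChemmineR::smiles2sdf(smis)
  suppressWarnings(ChemmineR::cid(sdf) <- names(smis))
  ob <- ChemmineR::propOB(sdf)
  for (i in seq_along(smis)) {
    f <- mol_formula(mol_from_smiles(smis[[i]]))
    expect_equal(mf_render(f), ob$formula[i], label = names(smis)[i])
    expect_equal(mf_mass(f), unname(ChemmineR::exactMassOB(sdf[i])),
                 tolerance = 2e-4, label = names(smis)[i])
  }
})

test_that("SMILES validation rejects malformed input by name", {
  expect_error(mol_from_smiles("C1CC"), "unparseable")
  expect_error(structure_record("x", "notasmiles("), "unparseable")
})

test_that("structure similarity is symmetric, bounded, and 1 on identity", {
  mols <- lapply(parent_smiles, mol_from_smiles)
  for (m in mols) expect_equal(structure_similarity(m, m), 1)
  set.seed(42)
  pairs <- t(utils::combn(length(mols), 2))
  for (k in seq_len(nrow(pairs))) {
    a <- mols[[pairs[k, 1]]]; b <- mols[[pairs[k, 2]]]
    s1 <- structure_similarity(a, b); s2 <- structure_similarity(b, a)
    expect_identical(s1, s2)
    expect_gte(s1, 0); expect_lt(s1, 1)
  }
  expect_lt(structure_similarity("C", "CCCCCCCCCC"), 1)
})

test_that("structure fit: substructure relations give 1, disjoint elements 0", {
  expect_equal(as.numeric(structure_fit("Nc1ccccc1", parent_smiles[["SMX"]])), 1)
  expect_equal(as.numeric(structure_fit(parent_smiles[["MET"]],
                                        parent_smiles[["MET"]])), 1)
  # no atoms of matching element
  expect_equal(as.numeric(structure_fit("OS(=O)O", "CCCC")), 0)
  f <- structure_fit("Cc1onc(N)c1", parent_smiles[["SMX"]])
  expect_equal(as.numeric(f), 1)  # azole ring substructure
  expect_lt(attr(f, "fit_parent"), 1)
})

test_that("MCS size equals the brute-force enumeration oracle on small pairs", {
  pairs <- list(
    c("CCO", "CCCO"),
    c("Nc1ccccc1", "c1ccncc1"),
    c("Cc1ccccc1", "Nc1ccccc1"),
    c("CC(C)O", "CC(N)C"),
    c("c1ccoc1", "c1ccsc1"),
    c("NCC(O)CO", "NCC(=O)CO"),
    c("CCOC(C)=O", "CCNC(C)=O"))
  for (p in pairs) {
    got <- mcs_size(p[1], p[2])
    expect_false(got$timed_out)
    expect_equal(got$size, mcs_oracle(p[1], p[2]),
                 label = paste(p, collapse = " vs "))
  }
})

test_that("log P predictions are deterministic and sanely ordered", {
  fle <- predict_logp(parent_smiles[["FLE"]])
  expect_equal(fle, 4.5, tolerance = 1)        # high-log P parent
  others <- predict_logp(parent_smiles[c("MET", "SMX", "PHE")])
  expect_true(all(others < fle))
  expect_gt(predict_logp("CCCCCCCCCC"), predict_logp("CO"))  # decane > methanol
  expect_identical(predict_logp(parent_smiles[["MET"]]),
                   predict_logp(parent_smiles[["MET"]]))
})

test_that("connectivity keys merge stereoisomers", {
  k1 <- inchikey_block("C[C@H](O)CC")
  k2 <- inchikey_block("C[C@@H](O)CC")
  expect_identical(k1, k2)
  expect_identical(nchar(k1), 14L)
  expect_false(inchikey_block("Nc1ccccc1") == k1)
})

test_that("structure records are consistent", {
  r <- structure_record("MET", parent_smiles[["MET"]])
  expect_equal(mf_render(r$formula), "C15H25NO3")
  expect_equal(r$monoisotopic_mass, mf_mass("C15H25NO3"), tolerance = 1e-9)
})
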