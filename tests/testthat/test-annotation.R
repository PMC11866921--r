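test_that("background removal follows the flanking-intensity rule", {
  cfg <- default_config()
  target <- ms2_spectrum("f", 200, cbind(c(50, 80, 120), c(100, 1000, 5000)))
  flank <- ms2_spectrum("f", 200, cbind(c(50.001, 80.001), c(90, 100)))
  out <- remove_background(target, list(flank), cfg)
  # peak 50: 100 <= 2 x 90 -> removed; peak 80: 1000 > 2 x 100 -> kept
  expect_false(any(abs(out$peaks[, 1] - 50) < 0.01))
  expect_true(any(abs(out$peaks[, 1] - 80) < 0.01))
  # no flanking: only the relative-intensity floor applies
  tgt2 <- ms2_spectrum("f", 200, cbind(c(50, 80, 120), c(40, 1000, 5000)))
  out2 <- remove_background(tgt2, list(), cfg)
  expect_equal(nrow(out2$peaks), 2)  # 40 < 1% of 5000 dropped
  # never adds peaks; idempotent
  expect_lte(nrow(out$peaks), nrow(target$peaks))
  again <- remove_background(out, list(flank), cfg)
  expect_identical(again$peaks, out$peaks)
})

test_that("formula enumeration finds known formulas and obeys filters", {
  res <- enumerate_formulas(94.0651, tol_mda = 5)
  expect_true("C6H7N" %in% res$formula)
  expect_true(all(res$rdbe >= 0))
  expect_true(all(abs(res$error_mda) <= 5))
  expect_false(is.unsorted(abs(res$error_mda)))
  # impossibly tight tolerance around a nonsense mass
  expect_equal(nrow(enumerate_formulas(94.5000, tol_mda = 0.01)), 0)
})

test_that("formula enumeration equals the exhaustive nested-loop oracle", {
  bounds <- c(C = 8, H = 16, N = 3, O = 4, S = 1, F = 3)
  set.seed(5)
  masses <- c(94.0651, 99.0553, runif(6, 60, 220))
  for (mz in masses) {
    got <- sort(enumerate_formulas(mz, 5, bounds = bounds)$formula)
    want <- enumerate_formulas_oracle(mz, 5, bounds)
    expect_identical(got, want, label = paste("mz", round(mz, 4)))
  }
})

test_that("fragment peaks get the closest subformula within tolerance", {
  # aniline: the 77.0386 peak is the C6H5+ cation, i.e. C6H4 + proton
  sp <- ms2_spectrum("f", 94.0651, cbind(c(77.0386, 94.0651, 200.0),
                                         c(500, 1000, 50)))
  ann <- annotate_fragments(sp, "C6H7N")
  a <- ann$assignments
  expect_equal(a$formula[abs(a$mz - 77.0386) < 1e-6], "C6H4")
  expect_true(is.na(a$formula[a$mz == 200.0]))  # heavier than precursor
  expect_lt(ann$explained_intensity_fraction, 1)
  # all peaks assigned -> explained fraction 1
  sp2 <- ms2_spectrum("f", 94.0651, cbind(94.0651, 1000))
  expect_equal(annotate_fragments(sp2, "C6H7N")$explained_intensity_fraction, 1)
  # assigned formulas are subformulas of the precursor
  prec <- mf_parse("C6H7N")
  for (f in a$formula[!is.na(a$formula)]) {
    sub <- mf_parse(f, names(tpscreen:::.tp_isotopes))
    expect_true(all(vapply(names(sub), function(e)
      sub[[e]] <= tpscreen:::.cnt(prec, e), logical(1))))
  }
})

test_that("bond-disconnection fragments match hand enumeration for ethanol", {
  fr <- fragment_structure("CCO", depth = 1)
  expect_setequal(fr$formula, c("C2H6O", "CH3", "C2H5", "CH3O", "HO"))
  fr0 <- fragment_structure("CCO", depth = 0)
  expect_equal(fr0$formula, "C2H6O")
  # monotone in depth
  n1 <- nrow(fragment_structure("CC(C)NCC(O)COc1ccc(CCOC)cc1", depth = 1))
  n2 <- nrow(fragment_structure("CC(C)NCC(O)COc1ccc(CCOC)cc1", depth = 2))
  expect_gte(n2, n1)
  # ring bonds break pairwise: benzene at depth 1 yields ring fragments
  frb <- fragment_structure("c1ccccc1", depth = 1)
  expect_true("C6H6" %in% frb$formula)
  expect_gt(nrow(frb), 1)
})

test_that("annotation scores are bounded, symmetric and self-consistent", {
  rec <- structure_record("ani", "Nc1ccccc1")
  fr <- fragment_structure(rec, depth = 2)
  pk <- cbind(fr$mz[1:5], c(1000, 800, 600, 400, 200))
  sp <- ms2_spectrum("f", adduct_mz("C6H7N"), pk)
  sc <- compound_annotation_score(sp, rec)
  expect_gte(sc, 0.9)
  expect_lte(sc, 1)
  # absent spectrum is NA, not zero
  expect_true(is.na(compound_annotation_score(NULL, rec)))
  expect_equal(ann_similarity(c("C6H4", "CH3"), c("CH3", "C6H4")), 1)
  expect_equal(ann_similarity(c("C6H4"), c("CH3")), 0)
  expect_identical(ann_similarity(c("A", "B"), c("B", "C")),
                   ann_similarity(c("B", "C"), c("A", "B")))
})

test_that("annotated spectra of planted TPs explain most intensity", {
  sim <- simulate_experiment(demo_simulation_spec(n_noise = 0, seed = 12))
  tt <- sim$truth[!is.na(sim$truth$smiles) & sim$truth$kind == "tp", ]
  tt <- tt[!duplicated(tt$group_id), ]
  spmap <- list()
  for (sp in sim$spectra) spmap[[sp$feature_group_id]] <- sp
  scores <- c()
  for (i in seq_len(min(6, nrow(tt)))) {
    sp <- spmap[[tt$group_id[i]]]
    if (is.null(sp)) next
    scores <- c(scores, compound_annotation_score(sp, tt$smiles[i]))
  }
  expect_gte(min(scores), 0.9)
})
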