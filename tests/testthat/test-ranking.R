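test_that("element filter removes forbidden-element candidates", {
  cand <- data.frame(candidate_id = c("a", "b", "c"),
                     formula = c("C7H7ClN2O", "C6H7N", "C3H9O3P"))
  out <- element_filter(cand)
  expect_identical(out$candidate_id, "b")
  expect_equal(attr(out, "n_removed"), 2L)
  # empty forbidden set is the identity
  out2 <- element_filter(cand, character(0))
  expect_equal(nrow(out2), 3)
})

test_that("elution-order filter tolerates moderate log P mismatches", {
  # candidates with known log P orderings relative to a mid-polarity parent
  parent <- structure_record("PHE", "CC1=CC(=O)N(c2ccccc2)N1C")
  hydrophobic <- data.frame(candidate_id = "h", smiles = "c1cc2ccc3cccc4ccc(c1)c2c34")  # pyrene
  dl <- predict_logp(hydrophobic$smiles) - predict_logp(parent$smiles)
  expect_gt(dl, 2)
  # elutes earlier despite much higher log P -> removed
  out <- elution_order_filter(hydrophobic, parent, feature_rt = 2,
                              parent_rt = 4.6, tol_logp = 2)
  expect_equal(nrow(out), 0)
  # later elution with higher log P -> kept
  out2 <- elution_order_filter(hydrophobic, parent, feature_rt = 8,
                               parent_rt = 4.6, tol_logp = 2)
  expect_equal(nrow(out2), 1)
  # small log P difference within tolerance -> kept either way
  mild <- data.frame(candidate_id = "m", smiles = "CC(=O)Nc1ccc(O)cc1")
  out3 <- elution_order_filter(mild, parent, feature_rt = 2,
                               parent_rt = 4.6, tol_logp = 2)
  expect_equal(nrow(out3), 1)
})

test_that("formula fit counts shared atoms including hydrogens", {
  smx <- "C10H11N3O3S"
  expect_equal(formula_fit("C6H7N", smx), 1)            # 14/14
  expect_equal(formula_fit("C10H11N3O4S", smx), 28 / 29)
  expect_equal(formula_fit(smx, smx), 1)
  expect_lt(formula_fit("C2F6", smx), 0.5)
})

test_that("threshold derivation uses the interpolated lower percentile", {
  sc <- data.frame(fit_compound = c(0.6, 0.7, 0.8, 0.9, 1.0))
  th <- derive_thresholds(sc, percentile = 5, metrics = "fit_compound",
                          guarantee_retention = FALSE)
  expect_equal(th$fit_compound, 0.62, tolerance = 1e-12)
  th0 <- derive_thresholds(sc, percentile = 0, metrics = "fit_compound",
                           guarantee_retention = FALSE)
  expect_equal(th0$fit_compound, 0.6)
  same <- data.frame(fit_compound = rep(0.8, 6))
  expect_equal(derive_thresholds(same, 5, "fit_compound")$fit_compound, 0.8)
  expect_warning(th_na <- derive_thresholds(sc[1:3, , drop = FALSE], 5),
                 "disabled")
  expect_null(th_na)
})

test_that("default thresholds jointly retain the calibration fraction", {
  set.seed(44)
  sc <- data.frame(fit_compound = runif(18, 0.4, 1),
                   sim_suspects = runif(18, 0.1, 0.9),
                   fit_formula = runif(18, 0.6, 1))
  sc$tp_score <- rowMeans(sc)
  th <- derive_thresholds(sc, percentile = 5)
  pass <- rep(TRUE, nrow(sc))
  for (m in names(th)) pass <- pass & sc[[m]] >= th[[m]] - 1e-12
  expect_gte(mean(pass), 0.95)
})

demo_rank_setup <- function() {
  parent <- structure_record("SMX", "Cc1onc(NS(=O)(=O)c2ccc(N)cc2)c1")
  parent$rt <- 5.1
  sus <- suspect_list(data.frame(
    suspect_id = c("s1", "s2"), parent_id = "SMX", kind = "structure",
    smiles = c("Nc1ccccc1", "Nc1ccc(cc1)S(=O)(=O)O"), formula = NA,
    sources = "LIT", label = ""))
  feat <- data.frame(group_id = "f", mz = adduct_mz("C6H7N"), rt = 4.1)
  list(parent = parent, sus = sus, feat = feat)
}

test_that("a candidate identical to a suspect gets sim_suspects 1 and survives", {
  s <- demo_rank_setup()
  cand <- data.frame(candidate_id = "ani", smiles = "Nc1ccccc1")
  th <- list(sim_suspects = 1)   # harshest conceivable threshold
  sc <- rank_candidates(s$feat, cand, s$parent, s$sus, NULL, th)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$sim_suspects, 1)
  expect_equal(sc$fit_compound, 1)
})

test_that("top-N keeps exactly 25 of many passing candidates", {
  s <- demo_rank_setup()
  decoys <- read_candidates(system.file("extdata", "decoy_structures.csv",
                                        package = "tpscreen"))
  cand <- data.frame(candidate_id = decoys$candidate_id,
                     smiles = decoys$smiles)
  sc <- rank_candidates(s$feat, cand, s$parent, s$sus, NULL, thresholds = NULL)
  expect_equal(nrow(sc), 25)
  expect_identical(sc$rank, 1:25)
  expect_true(all(diff(sc$tp_score) <= 1e-12))
})

test_that("candidates without MS2 stay rankable via the absent-component rule", {
  s <- demo_rank_setup()
  cand <- data.frame(candidate_id = "ani", smiles = "Nc1ccccc1")
  sc <- rank_candidates(s$feat, cand, s$parent, s$sus, spectrum = NULL,
                        thresholds = NULL)
  expect_true(is.na(sc$ann_compound))
  expect_equal(sc$tp_score, mean(c(sc$fit_compound, sc$sim_suspects)))
})

test_that("raising thresholds never adds candidates; filters commute", {
  s <- demo_rank_setup()
  decoys <- read_candidates(system.file("extdata", "decoy_structures.csv",
                                        package = "tpscreen"))
  cand <- data.frame(candidate_id = decoys$candidate_id,
                     smiles = decoys$smiles)
  lo <- rank_candidates(s$feat, cand, s$parent, s$sus, NULL,
                        list(tp_score = 0.2))
  hi <- rank_candidates(s$feat, cand, s$parent, s$sus, NULL,
                        list(tp_score = 0.5))
  expect_true(all(hi$candidate_id %in% lo$candidate_id))
  # element and elution filters commute on the output set
  cand$formula <- vapply(cand$smiles, function(x)
    mf_render(mol_formula(mol_from_smiles(x))), character(1))
  a <- elution_order_filter(element_filter(cand), s$parent, 4.1, 5.1)
  b <- element_filter(elution_order_filter(cand, s$parent, 4.1, 5.1))
  expect_setequal(a$candidate_id, b$candidate_id)
})

test_that("proposed structures are checked against the assigned formula", {
  s <- demo_rank_setup()
  props <- data.frame(candidate_id = c("good", "off_by_ch2"),
                      smiles = c("Nc1ccccc1", "Cc1ccccc1N"))
  out <- score_proposed_structures(s$feat, props, "C6H7N", s$parent, s$sus)
  expect_equal(out$candidate_id, "good")
  expect_match(attr(out, "rejected"), "off_by_ch2")
  empty <- score_proposed_structures(s$feat, props[0, ], "C6H7N", s$parent)
  expect_equal(nrow(empty), 0)
})

test_that("the true planted structure outranks decoys with MS2 evidence", {
  set.seed(7)
  sim <- simulate_experiment(demo_simulation_spec(n_noise = 0, seed = 7))
  tt <- sim$truth[!is.na(sim$truth$smiles) & sim$truth$kind == "tp", ]
  tt <- tt[!duplicated(tt$group_id), ]
  spmap <- list(); for (sp in sim$spectra) spmap[[sp$feature_group_id]] <- sp
  decoys <- read_candidates(system.file("extdata", "decoy_structures.csv",
                                        package = "tpscreen"))
  parents <- demo_parents()
  sus <- demo_suspects(seed = 7, hidden = character(0))
  wins <- 0L; n <- 0L
  for (i in sample(nrow(tt), 5)) {
    pid <- tt$parent_id[i]
    parent <- structure_record(pid, parents$smiles[parents$parent_id == pid])
    parent$rt <- parents$rt[parents$parent_id == pid]
    feat <- sim$features[sim$features$group_id == tt$group_id[i], ]
    cand <- rbind(data.frame(candidate_id = decoys$candidate_id,
                             smiles = decoys$smiles),
                  data.frame(candidate_id = "TRUE_TP", smiles = tt$smiles[i]))
    sc <- rank_candidates(feat, cand, parent, sus,
                          spmap[[tt$group_id[i]]], thresholds = NULL)
    n <- n + 1L
    if (sc$candidate_id[1] == "TRUE_TP" || ("TRUE_TP" %in% sc$candidate_id &&
                                             sc$rank[sc$candidate_id == "TRUE_TP"] <= 3))
      wins <- wins + 1L
  }
  expect_gte(wins / n, 0.8)
})
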