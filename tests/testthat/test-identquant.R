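test_that("isotope fit score is zero on identity and monotone in the gap", {
  p <- isotope_pattern("C10H11N3O3S", 2)
  expect_equal(isotope_fit_score(p, p), 0)
  # uniform 5% relative error on M+1 and M+2 stays well below 100
  m <- p; m$abundance[2:3] <- m$abundance[2:3] * 1.05
  expect_lt(isotope_fit_score(m, p), 100)
  # a missing M+2 where theory expects 5% scores worse than a smaller gap
  half <- p; half$abundance[3] <- p$abundance[3] / 2
  gone <- p; gone$abundance[3] <- 0
  expect_gt(isotope_fit_score(gone, p), isotope_fit_score(half, p))
  expect_gt(isotope_fit_score(gone, p), 0)
})

test_that("standard confirmation applies RT, m/z and isotope criteria", {
  cfg <- default_config()
  std <- list(rt = 4.0, formula = "C6H7N")
  feat_ok <- list(mz = adduct_mz("C6H7N") + 0.001, rt = 4.05)
  expect_true(confirm_with_standard(feat_ok, std, NULL, cfg)$confirmed)
  feat_rt <- list(mz = adduct_mz("C6H7N"), rt = 4.3)
  expect_false(confirm_with_standard(feat_rt, std, NULL, cfg)$confirmed)
  feat_mz <- list(mz = adduct_mz("C6H7N") + 0.007, rt = 4.0)
  expect_false(confirm_with_standard(feat_mz, std, NULL, cfg)$confirmed)
  # isotope criterion engages when a measured pattern is supplied
  bad_pat <- isotope_pattern("C6H7N", 2)
  bad_pat$abundance[2:3] <- c(0.5, 0.4)
  res <- confirm_with_standard(feat_ok, std, bad_pat, cfg)
  expect_false(res$confirmed)
  expect_false(res$evidence$isotope_match)
})

test_that("identification levels follow the evidence hierarchy", {
  expect_equal(assign_level(list(standard_confirmed = TRUE))$level, "1")
  expect_equal(assign_level(list(standard_confirmed = TRUE,
                                 competing_isomers = TRUE))$level, "3a")
  expect_equal(assign_level(list(library_match = TRUE))$level, "2")
  expect_equal(assign_level(list(has_structure_candidate = TRUE,
                                 ann_score = 0.8))$level, "3b")
  expect_equal(assign_level(list(has_structure_candidate = TRUE,
                                 ann_score = NA_real_))$level, "3b")
  expect_equal(assign_level(list(n_formula_candidates = 1L))$level, "4")
  expect_equal(assign_level(list(n_formula_candidates = 7L))$level, "5")
  expect_equal(assign_level(list())$level, "5")
  expect_lt(level_compare("1", "3b"), 0)
  expect_gt(level_compare("5", "3a"), 0)
})

test_that("calibration acceptance enforces the three curve criteria", {
  conc <- 250 / 2^(0:4)
  perfect <- data.frame(conc_ugL = conc, response = 100 * conc)
  cv <- fit_calibration(perfect, "p")
  expect_true(cv$accepted)
  expect_equal(cv$slope, 100, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(as.numeric(quantify(5000, cv)), 50, tolerance = 1e-9)
  # four points only
  cv4 <- fit_calibration(perfect[1:4, ], "p")
  expect_false(cv4$accepted)
  expect_match(cv4$reason, "5 calibration points")
  expect_error(quantify(5000, cv4), "rejected")
  # a 40% residual on one point
  bad <- perfect; bad$response[3] <- bad$response[3] * 1.4
  cvb <- fit_calibration(bad, "p")
  expect_false(cvb$accepted)
  # scattered responses fail the R-squared criterion
  set.seed(2)
  noisy <- data.frame(conc_ugL = conc, response = 100 * conc * runif(5, 0.5, 2))
  expect_false(fit_calibration(noisy, "p")$accepted)
  # acceptance is monotone: adding a perfectly fitting point cannot reject
  more <- rbind(perfect, data.frame(conc_ugL = 500, response = 50000))
  expect_true(fit_calibration(more, "p")$accepted)
  # extrapolation is flagged
  expect_true(attr(quantify(100 * 400, cv), "extrapolated"))
})

test_that("semi-quantitation dispatches to standards or predicted RFs", {
  conc <- 150 / 2^(0:4)
  curve <- fit_calibration(data.frame(conc_ugL = conc, response = 2000 * conc),
                           "tp")
  q1 <- semi_quantify(2000 * 75, "C6H7N", curve = curve)
  expect_equal(q1$provenance, "standard")
  expect_equal(q1$conc_ugL, 75, tolerance = 1e-9)
  expect_equal(q1$conc_uM, 75 / mf_mass("C6H7N"), tolerance = 1e-9)
  # default predictor: parent response factor at equal molarity
  q2 <- semi_quantify(5e5 * 0.3, "C6H7N", rf_predicted = 5e5)
  expect_equal(q2$provenance, "predicted")
  expect_equal(q2$conc_uM, 0.3, tolerance = 1e-12)
  expect_equal(q2$uncertainty_band, c(0.3 / 5, 0.3 * 5), tolerance = 1e-12)
  expect_error(semi_quantify(100, ""), "cannot quantify")
})

test_that("removal statistics match the textbook pooled t-test", {
  # worked example: groups (90,100) vs (70,80)
  st <- removal_stats(c(90, 100), c(70, 80))
  expect_equal(st$t, 2.828, tolerance = 1e-3)
  expect_equal(st$df, 2)
  expect_equal(st$p_value, 0.1056, tolerance = 1e-3)
  expect_false(st$significant)
  o <- pooled_t_oracle(c(90, 100), c(70, 80))
  expect_equal(st$t, o$t, tolerance = 1e-9)
  expect_equal(st$p_value, o$p, tolerance = 1e-9)
  # random agreement with the oracle
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(4, 100, 10); y <- rnorm(3, 80, 10)
    st <- removal_stats(x, y)
    o <- pooled_t_oracle(x, y)
    expect_equal(st$t, o$t, tolerance = 1e-9)
    expect_equal(st$p_value, o$p, tolerance = 1e-9)
  }
  # arithmetic and degenerate cases
  expect_equal(removal_stats(c(150, 150), c(33, 33))$removal_pct, 78,
               tolerance = 1e-9)
  same <- removal_stats(c(100, 100), c(100, 100))
  expect_equal(same$removal_pct, 0)
  expect_equal(same$p_value, 1)
  single <- removal_stats(100, 60)
  expect_equal(single$removal_pct, 40)
  expect_true(is.na(single$p_value))
})

test_that("mass balances follow the molar bookkeeping", {
  mb0 <- mass_balance(0.5, data.frame(tp_id = character(0),
                                      conc_uM = numeric(0),
                                      provenance = character(0)))
  expect_equal(mb0$explained_fraction, 0)
  mb1 <- mass_balance(0.5, data.frame(tp_id = "t", conc_uM = 0.5,
                                      provenance = "standard"))
  expect_equal(mb1$explained_fraction, 100)
  # excluded TPs and shared parents
  mb2 <- mass_balance(1, data.frame(tp_id = c("a", "b"),
                                    conc_uM = c(0.3, 0.4),
                                    provenance = "predicted",
                                    exclude = c(FALSE, TRUE)))
  expect_equal(mb2$explained_fraction, 30)
  mb3 <- mass_balance(1, data.frame(tp_id = "shared", conc_uM = 0.5,
                                    provenance = "predicted",
                                    n_parents = 2L))
  expect_equal(mb3$explained_fraction, 25)
  expect_warning(mb4 <- mass_balance(1, data.frame(
    tp_id = "shared", conc_uM = 0.5, provenance = "predicted",
    n_parents = 2L), shared = "full"), "shared")
  expect_equal(mb4$explained_fraction, 50)
  # undefined when removal is not positive
  und <- mass_balance(0, data.frame(tp_id = "t", conc_uM = 1,
                                    provenance = "standard"))
  expect_false(und$defined)
  expect_true(is.na(und$explained_fraction))
})
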