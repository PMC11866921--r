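# Identification-confidence assignment, calibration and semi-quantitation,
# molar mass balances and parent-removal statistics.

.level_order <- c("1", "2", "3a", "3b", "4", "5")

#' Isotope-pattern fit score
#'
#' Goodness of fit between a measured and a theoretical isotope pattern:
#' 1000 times the root-mean-square deviation of fractional abundances
#' (each pattern normalized to sum 1 over offsets 0..2). Zero for
#' identical patterns; the acceptance threshold of 100 corresponds to
#' roughly 10% per-peak deviations.
#'
#' @param measured,theoretical `iso_pattern` objects (offsets 0..2 or
#'   more).
#' @return Non-negative score; lower is better.
#' @export
isotope_fit_score <- function(measured, theoretical) {
  take <- function(p) {
    v <- setNames(rep(0, 3), 0:2)
    sel <- p$offset <= 2
    v[as.character(p$offset[sel])] <- p$abundance[sel]
    v / sum(v)
  }
  m <- take(measured); t <- take(theoretical)
  1000 * sqrt(mean((m - t)^2))
}

#' Confirm a feature against a reference standard
#'
#' Confirmation requires retention time within `rt_tol_min`, accurate m/z
#' within `mz_tol_mda`, and an isotope-pattern fit score below
#' `msigma_max` (skipped when no measured pattern is supplied). Evidence
#' is itemized.
#'
#' @param feature Feature row (needs `mz`, `rt`).
#' @param standard List/row with `rt` and `formula` (or `smiles`).
#' @param measured_pattern Optional measured `iso_pattern`.
#' @param config Configuration.
#' @return List with `confirmed` (logical) and `evidence` (named logical
#'   vector plus the observed deviations).
#' @export
confirm_with_standard <- function(feature, standard, measured_pattern = NULL,
                                  config = default_config()) {
  f <- standard$formula
  if ((is.null(f) || is.na(f)) && !is.null(standard$smiles))
    f <- mf_render(mol_formula(mol_from_smiles(standard$smiles)))
  smz <- adduct_mz(mf_parse(f, names(.tp_isotopes)), config$adduct)
  drt <- abs(feature$rt - standard$rt)
  dmz <- abs(feature$mz - smz) * 1000
  ok_rt <- drt <= config$rt_tol_min
  ok_mz <- dmz <= config$mz_tol_mda
  fit <- NA_real_
  ok_iso <- TRUE
  if (!is.null(measured_pattern)) {
    fit <- isotope_fit_score(measured_pattern,
                             isotope_pattern(mf_parse(f, names(.tp_isotopes)), 2))
    ok_iso <- fit < config$msigma_max
  }
  list(confirmed = ok_rt && ok_mz && ok_iso,
       evidence = list(rt_match = ok_rt, mz_match = ok_mz,
                       isotope_match = ok_iso, delta_rt_min = drt,
                       delta_mz_mda = dmz, isotope_fit = fit))
}

#' Assign an identification confidence level
#'
#' Levels follow the standard communication scheme: 1 = confirmed by
#' reference standard with a unique structure; 2 = MS2 library match;
#' 3a = standard-confirmed but not distinguishable from isomeric
#' suspects; 3b = tentative structure candidate with annotation support;
#' 4 = unambiguous molecular formula (single surviving formula with
#' passing isotope fit); 5 = exact mass only.
#'
#' @param evidence List with logical/values: `standard_confirmed`,
#'   `competing_isomers`, `library_match`, `has_structure_candidate`,
#'   `ann_score` (may be `NA`), `n_formula_candidates`,
#'   `isotope_fit_ok`.
#' @param ann_floor Minimum annotation score supporting a tentative
#'   structure (level 3b); structure candidates without MS2 also qualify.
#' @return A `confidence_level`: list with `level` and `evidence`.
#' @export
assign_level <- function(evidence, ann_floor = 0.2) {
  ev <- modifyList(list(standard_confirmed = FALSE, competing_isomers = FALSE,
                        library_match = FALSE, has_structure_candidate = FALSE,
                        ann_score = NA_real_, n_formula_candidates = NA_integer_,
                        isotope_fit_ok = TRUE), evidence)
  level <-
    if (ev$standard_confirmed && !ev$competing_isomers) "1"
    else if (ev$library_match) "2"
    else if (ev$standard_confirmed) "3a"
    else if (ev$has_structure_candidate &&
             (is.na(ev$ann_score) || ev$ann_score >= ann_floor)) "3b"
    else if (!is.na(ev$n_formula_candidates) && ev$n_formula_candidates == 1 &&
             ev$isotope_fit_ok) "4"
    else "5"
  structure(list(level = level, evidence = ev), class = "confidence_level")
}

#' @export
print.confidence_level <- function(x, ...) {
  cat("<identification level ", x$level, ">\n", sep = "")
  invisible(x)
}

#' Compare confidence levels
#'
#' @param a,b Level strings or `confidence_level` objects.
#' @return Negative/zero/positive when `a` is better/equal/worse than `b`.
#' @export
level_compare <- function(a, b) {
  lv <- function(x) match(if (inherits(x, "confidence_level")) x$level else x,
                          .level_order)
  lv(a) - lv(b)
}

# ---- calibration and quantitation ------------------------------------------

#' Fit a calibration curve
#'
#' Unweighted ordinary least squares of response on concentration
#' (optionally 1/x weighted). The curve is rejected, with a named reason,
#' unless it has at least 5 points, R-squared >= 0.99, and every relative
#' residual at most 30%.
#'
#' @param points Data frame with `conc_ugL` and `response`.
#' @param analyte_id Identifier for error messages.
#' @param channel Response channel, `"monoisotopic"` or `"M+2"`.
#' @param weighted Use 1/x weights.
#' @return A `calibration_curve`: slope, intercept, r_squared,
#'   max_abs_residual_fraction, `accepted`, `reason`, and the calibrated
#'   range.
#' @export
fit_calibration <- function(points, analyte_id = "analyte",
                            channel = c("monoisotopic", "M+2"),
                            weighted = FALSE) {
  channel <- match.arg(channel)
  accepted <- TRUE; reason <- ""
  n <- nrow(points)
  fitv <- NULL
  if (n < 5) {
    accepted <- FALSE; reason <- "fewer than 5 calibration points"
    sl <- int <- r2 <- maxres <- NA_real_
  } else {
    w <- if (weighted) 1 / points$conc_ugL else rep(1, n)
    fit <- lm(response ~ conc_ugL, data = points, weights = w)
    sl <- unname(coef(fit)[2]); int <- unname(coef(fit)[1])
    fitv <- int + sl * points$conc_ugL
    r2 <- 1 - sum((points$response - fitv)^2) /
      sum((points$response - mean(points$response))^2)
    maxres <- max(abs(points$response - fitv) / abs(fitv))
    if (r2 < 0.99) { accepted <- FALSE; reason <- "R-squared below 0.99" }
    else if (maxres > 0.30) { accepted <- FALSE; reason <- "residuals above 30%" }
  }
  structure(list(analyte_id = analyte_id, response_channel = channel,
                 points = points, slope = sl, intercept = int,
                 r_squared = r2, max_abs_residual_fraction = maxres,
                 range_ugL = if (n) range(points$conc_ugL) else c(NA, NA),
                 accepted = accepted, reason = reason),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration> ", x$analyte_id, " [", x$response_channel, "]: ",
      if (x$accepted) "accepted" else paste0("REJECTED (", x$reason, ")"),
      "\n", sep = "")
  if (x$accepted)
    cat("  slope ", signif(x$slope, 6), ", intercept ", signif(x$intercept, 6),
        ", R2 ", round(x$r_squared, 5), "\n", sep = "")
  invisible(x)
}

#' Quantify a response with a calibration curve
#'
#' Inverts the calibration line. Using a rejected curve is an error;
#' responses outside the calibrated range are flagged as extrapolated.
#'
#' @param response Measured response.
#' @param curve A `calibration_curve`.
#' @return Concentration in ug/L with attribute `extrapolated`.
#' @export
quantify <- function(response, curve) {
  if (!curve$accepted)
    stop("calibration curve for ", curve$analyte_id, " was rejected: ",
         curve$reason)
  conc <- (response - curve$intercept) / curve$slope
  extra <- conc < curve$range_ugL[1] | conc > curve$range_ugL[2]
  structure(conc, extrapolated = extra)
}

#' Semi-quantify a TP
#'
#' Uses the TP's own standard curve when available (provenance
#' `standard`); otherwise divides the response by a predicted response
#' factor (provenance `predicted`; the default predictor reuses the
#' parent's response factor, and predicted concentrations carry a
#' documented factor-`rf_uncertainty_factor` uncertainty band).
#' Concentrations are converted to uM via the monoisotopic-derived molar
#' mass.
#'
#' @param response Feature response (intensity).
#' @param formula TP molecular formula (string or `mol_formula`);
#'   required.
#' @param curve Optional accepted `calibration_curve` (response vs ug/L).
#' @param rf_predicted Predicted response factor (counts per uM), used
#'   when no curve is given.
#' @param config Configuration.
#' @return List: `conc_uM`, `conc_ugL` (when defined), `provenance`, and
#'   `uncertainty_band` (uM bounds for predicted values).
#' @export
semi_quantify <- function(response, formula, curve = NULL,
                          rf_predicted = NULL, config = default_config()) {
  if (is.null(formula) || (is.character(formula) && !nzchar(formula)))
    stop("cannot quantify without a structure or formula")
  mw <- mf_mass(formula)
  if (!is.null(curve)) {
    ugL <- as.numeric(quantify(response, curve))
    uM <- ugL / mw
    return(list(conc_uM = uM, conc_ugL = ugL, provenance = "standard",
                uncertainty_band = c(uM, uM)))
  }
  if (is.null(rf_predicted))
    stop("no calibration curve and no predicted response factor")
  uM <- response / rf_predicted
  k <- config$rf_uncertainty_factor
  list(conc_uM = uM, conc_ugL = uM * mw, provenance = "predicted",
       uncertainty_band = c(uM / k, uM * k))
}

# ---- removal statistics and mass balance -----------------------------------

#' Parent removal with significance
#'
#' Removal percentage `100 x (1 - mean(2 h) / mean(0 h))` per parent and
#' condition, with a pooled-variance two-sample t-test (two-sided) between
#' the 0 h and 2 h replicate concentrations. With a single replicate the
#' removal is still computed but significance is unavailable.
#'
#' @param conc0,conc2 Numeric vectors of replicate concentrations at 0 h
#'   and 2 h.
#' @param alpha Significance level for the `n.s.` flag.
#' @return Data frame row: `removal_pct`, `t`, `df`, `p_value`,
#'   `significant`.
#' @export
removal_stats <- function(conc0, conc2, alpha = 0.05) {
  rem <- 100 * (1 - mean(conc2) / mean(conc0))
  if (length(conc0) < 2 || length(conc2) < 2 ||
      (stats::var(conc0) == 0 && stats::var(conc2) == 0)) {
    if (isTRUE(all.equal(mean(conc0), mean(conc2))))
      return(data.frame(removal_pct = rem, t = 0, df = NA_real_, p_value = 1,
                        significant = FALSE))
    return(data.frame(removal_pct = rem, t = NA_real_, df = NA_real_,
                      p_value = NA_real_, significant = NA))
  }
  tt <- t.test(conc0, conc2, var.equal = TRUE)
  data.frame(removal_pct = rem, t = unname(tt$statistic),
             df = unname(tt$parameter), p_value = tt$p.value,
             significant = tt$p.value <= alpha)
}

#' Molar mass balance
#'
#' Fraction of the molar parent removal explained by the summed TP molar
#' concentrations: `100 x sum(TP uM) / parent removal uM`. TPs can be
#' excluded from the sum (e.g. when their formation cannot be separated
#' from other TPs); TPs shared between parents are split equally or
#' attributed fully to each parent with a warning, per `shared`.
#'
#' @param parent_removed_uM Molar parent removal (> 0 for a defined
#'   balance).
#' @param tp_conc Data frame: `tp_id`, `conc_uM`, `provenance`, optional
#'   logical `exclude` and integer `n_parents` (shared-parent count).
#' @param parent_id,condition Labels carried through.
#' @param shared `"split"` (divide shared TPs by their parent count) or
#'   `"full"` (attribute fully, with a warning).
#' @return A `mass_balance`: list with the inputs, per-TP contributions
#'   and `explained_fraction` (percent; `NA` with `defined = FALSE` when
#'   removal is not positive).
#' @export
mass_balance <- function(parent_removed_uM, tp_conc,
                         parent_id = NA, condition = NA,
                         shared = c("split", "full")) {
  shared <- match.arg(shared)
  if (!nrow(tp_conc)) tp_conc <- data.frame(tp_id = character(0),
                                            conc_uM = numeric(0),
                                            provenance = character(0))
  if (!"exclude" %in% names(tp_conc))
    tp_conc$exclude <- rep(FALSE, nrow(tp_conc))
  if (!"n_parents" %in% names(tp_conc))
    tp_conc$n_parents <- rep(1L, nrow(tp_conc))
  stopifnot(all(tp_conc$conc_uM >= 0, na.rm = TRUE))
  contrib <- ifelse(tp_conc$exclude, 0,
                    if (shared == "split") tp_conc$conc_uM / tp_conc$n_parents
                    else tp_conc$conc_uM)
  if (shared == "full" && any(tp_conc$n_parents > 1 & !tp_conc$exclude))
    warning("TP(s) shared between parents attributed fully to each parent: ",
            paste(tp_conc$tp_id[tp_conc$n_parents > 1], collapse = ", "))
  defined <- is.finite(parent_removed_uM) && parent_removed_uM > 0
  ef <- if (defined) 100 * sum(contrib) / parent_removed_uM else NA_real_
  structure(list(parent_id = parent_id, condition = condition,
                 parent_removed_uM = parent_removed_uM,
                 tp_contributions = cbind(tp_conc, contribution_uM = contrib),
                 explained_fraction = ef, defined = defined),
            class = "mass_balance")
}

#' @export
print.mass_balance <- function(x, ...) {
  cat("<mass balance> ", x$parent_id, " / ", x$condition, ": ",
      if (x$defined) paste0(round(x$explained_fraction, 1), "% explained")
      else "undefined (no significant parent removal)", "\n", sep = "")
  invisible(x)
}
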