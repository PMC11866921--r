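# Ranking of candidate structures/formulas for unknown features: element
# and elution-order filters, the fit metrics, suspect-derived thresholds,
# the combined TP score, and the top-N cut.

#' Element filter for candidates
#'
#' Removes candidates whose formula contains any forbidden element
#' (defaults: Cl, Br, Si, P -- unlikely in TPs of the studied parents).
#'
#' @param candidates Data frame with a `formula` column.
#' @param forbidden Character vector of element symbols.
#' @return Filtered data frame; removed count in attribute `n_removed`.
#' @export
element_filter <- function(candidates, forbidden = c("Cl", "Br", "Si", "P")) {
  if (!nrow(candidates) || !length(forbidden)) {
    attr(candidates, "n_removed") <- 0L
    return(candidates)
  }
  has_forbidden <- vapply(candidates$formula, function(f) {
    cnt <- tryCatch(mf_parse(f, names(.tp_isotopes)), error = function(e) NULL)
    if (is.null(cnt)) return(TRUE)
    any(names(cnt) %in% forbidden)
  }, logical(1))
  out <- candidates[!has_forbidden, , drop = FALSE]
  attr(out, "n_removed") <- sum(has_forbidden)
  out
}

#' Elution-order filter
#'
#' Under the reversed-phase assumption (higher log P elutes later), a
#' candidate is removed only when the sign of its log P difference from
#' the parent contradicts the sign of the retention-time difference AND
#' the log P difference exceeds `tol_logp` (considerable tolerance for
#' prediction errors). Candidates whose log P cannot be predicted are
#' retained and flagged (fail-open).
#'
#' @param candidates Data frame with a `smiles` column.
#' @param parent Parent `structure_record` (or SMILES).
#' @param feature_rt,parent_rt Retention times (minutes).
#' @param tol_logp Tolerance on the log P difference (default 2).
#' @return Filtered data frame with a `logp_flag` column for failed
#'   predictions; removed count in attribute `n_removed`.
#' @export
elution_order_filter <- function(candidates, parent, feature_rt, parent_rt,
                                 tol_logp = 2) {
  if (!nrow(candidates)) {
    attr(candidates, "n_removed") <- 0L
    return(candidates)
  }
  plogp <- if (inherits(parent, "structure_record")) record_logp(parent)
           else predict_logp(parent)
  clogp <- suppressWarnings(predict_logp(candidates$smiles))
  dl <- clogp - plogp
  drt <- feature_rt - parent_rt
  contradicts <- !is.na(dl) & sign(dl) != 0 & sign(drt) != 0 &
    sign(dl) != sign(drt) & abs(dl) > tol_logp
  out <- candidates[!contradicts, , drop = FALSE]
  out$logp_flag <- is.na(clogp[!contradicts])
  attr(out, "n_removed") <- sum(contradicts)
  out
}

#' Formula fit
#'
#' Fraction of the candidate's atoms (hydrogens included) shared with the
#' parent formula: `sum_e min(cand_e, parent_e) / sum_e cand_e`. Equals 1
#' exactly when the candidate is element-wise contained in the parent.
#'
#' @param candidate_formula,parent_formula Formulas (objects or strings).
#' @return Fit in \[0, 1\].
#' @export
formula_fit <- function(candidate_formula, parent_formula) {
  cf <- mf_parse(candidate_formula, names(.tp_isotopes))
  pf <- mf_parse(parent_formula, names(.tp_isotopes))
  els <- union(names(cf), names(pf))
  shared <- sum(vapply(els, function(e) min(.cnt(cf, e), .cnt(pf, e)), integer(1)))
  shared / sum(cf)
}

#' Derive ranking thresholds from suspect data
#'
#' Ranking metrics are first evaluated on suspect-matched candidates (for
#' which the TP hypothesis is considered credible); the lower `percentile`
#' of each metric over that calibration set becomes the elimination
#' threshold, so at the default 5th percentile at least 95% of the
#' calibration suspects pass every threshold by construction.
#'
#' @param suspect_scores Data frame of `CandidateScore` rows for
#'   suspect-matched candidates.
#' @param percentile Lower percentile (default 5, linear interpolation).
#' @param metrics Metric columns to threshold.
#' @param min_n Minimum calibration records; below it thresholds are
#'   disabled with a warning.
#' @param guarantee_retention Relax the raw percentile thresholds
#'   minimally until at least `100 - percentile` percent of the
#'   calibration records pass all thresholds jointly (default). With
#'   finitely many records the per-metric percentiles alone can jointly
#'   exclude more than `percentile` percent; the relaxation restores the
#'   retention guarantee by construction. `FALSE` returns the raw
#'   interpolated percentiles.
#' @return Named list of thresholds (or `NULL` when disabled).
#' @export
derive_thresholds <- function(suspect_scores, percentile = 5,
                              metrics = c("fit_compound", "sim_suspects",
                                          "ann_compound", "fit_formula",
                                          "ann_formula", "tp_score"),
                              min_n = 5L, guarantee_retention = TRUE) {
  if (is.null(suspect_scores) || nrow(suspect_scores) < min_n) {
    warning("too few suspect-matched records (",
            if (is.null(suspect_scores)) 0 else nrow(suspect_scores),
            " < ", min_n, "); ranking thresholds disabled")
    return(NULL)
  }
  out <- list()
  for (m in intersect(metrics, names(suspect_scores))) {
    v <- suspect_scores[[m]]
    v <- v[!is.na(v)]
    if (length(v) >= min_n)
      out[[m]] <- unname(quantile(v, percentile / 100, type = 7))
  }
  if (!guarantee_retention) return(out)
  # relax thresholds minimally until at least (100 - percentile)% of the
  # calibration records pass all of them jointly
  joint_pass <- function(th) {
    pass <- rep(TRUE, nrow(suspect_scores))
    for (m in names(th)) {
      v <- suspect_scores[[m]]
      pass <- pass & (is.na(v) | v >= th[[m]] - 1e-12)
    }
    pass
  }
  target <- ceiling((1 - percentile / 100) * nrow(suspect_scores))
  pass <- joint_pass(out)
  while (sum(pass) < target) {
    fail <- which(!pass)
    ts <- suspect_scores$tp_score[fail]
    ts[is.na(ts)] <- -Inf
    best <- fail[which.max(ts)]
    for (m in names(out)) {
      v <- suspect_scores[[m]][best]
      if (!is.na(v) && v < out[[m]]) out[[m]] <- v
    }
    pass <- joint_pass(out)
  }
  out
}

.combine_tp_score <- function(components, weights = NULL) {
  v <- unlist(components)
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  if (is.null(weights)) return(mean(v))
  w <- weights[names(v)]
  w[is.na(w)] <- 1
  sum(v * w) / sum(w)
}

#' Score and rank candidates for an unknown feature
#'
#' Computes, per candidate: `fit_formula` (always); for compound
#' candidates additionally `fit_compound` (MCS fit against the parent),
#' `sim_suspects` (maximum fingerprint similarity to the parent's
#' structure suspects) and `ann_compound` (in-silico annotation score
#' against the feature's MS2, `NA` when no spectrum exists). The TP score
#' is the mean of the available components (absent components are
#' excluded, mirroring the prioritization of features without MS2 data).
#' Candidates below any suspect-derived threshold are dropped, the rest
#' ranked by TP score with ties broken by `fit_formula` then candidate id,
#' and the top `top_n` kept. Per-stage survivor counts are attached as
#' attribute `stages`.
#'
#' @param feature One-row slice of a `feature_table` (or list with `mz`,
#'   `rt`, `group_id`).
#' @param candidates Candidate data frame (`candidate_id` plus `smiles`
#'   and/or `formula`).
#' @param parent Parent `structure_record`.
#' @param suspects `suspect_list` (the parent's structure suspects are
#'   used for `sim_suspects`).
#' @param spectrum Cleaned `ms2_spectrum` for the feature, or `NULL`.
#' @param thresholds Named list from [derive_thresholds()] (or `NULL`).
#' @param config Configuration.
#' @param parent_rt Parent retention time (minutes); taken from
#'   `parent$rt` when omitted.
#' @return Data frame of `CandidateScore` rows, ranked.
#' @export
rank_candidates <- function(feature, candidates, parent, suspects = NULL,
                            spectrum = NULL, thresholds = NULL,
                            config = default_config(), parent_rt = NULL) {
  stages <- c(input = nrow(candidates))
  if (!"formula" %in% names(candidates)) candidates$formula <- NA_character_
  if (!"smiles" %in% names(candidates)) candidates$smiles <- NA_character_
  is_cmp <- !is.na(candidates$smiles) & nzchar(candidates$smiles)
  for (i in which(is_cmp & (is.na(candidates$formula) | !nzchar(candidates$formula))))
    candidates$formula[i] <- mf_render(mol_formula(mol_from_smiles(candidates$smiles[i])))

  candidates <- element_filter(candidates, config$forbidden_elements)
  stages <- c(stages, element_filter = nrow(candidates))
  is_cmp <- !is.na(candidates$smiles) & nzchar(candidates$smiles)
  cmp <- candidates[is_cmp, , drop = FALSE]
  fml <- candidates[!is_cmp, , drop = FALSE]
  prt <- parent_rt %||% parent$rt %||% feature$rt
  if (nrow(cmp))
    cmp <- elution_order_filter(cmp, parent, feature$rt, prt,
                                tol_logp = config$tol_logp)
  stages <- c(stages, elution_filter = nrow(cmp) + nrow(fml))

  pstr <- if (!is.null(suspects) && nrow(suspects))
    as.data.frame(suspects)[as.data.frame(suspects)$kind == "structure" &
                              as.data.frame(suspects)$parent_id == parent$id, ,
                            drop = FALSE]
  else data.frame(smiles = character(0))

  score_one <- function(row, compound) {
    ff <- formula_fit(row$formula, parent$formula)
    fc <- ss <- ac <- af <- NA_real_
    if (compound) {
      fc <- as.numeric(structure_fit(row$smiles, parent$mol,
                                     direction = config$fit_direction,
                                     time_budget_s = config$mcs_time_budget_s))
      ss <- if (nrow(pstr)) max(vapply(pstr$smiles, function(s)
        structure_similarity(row$smiles, s), numeric(1))) else NA_real_
      ac <- compound_annotation_score(spectrum, row$smiles, config)
      comp <- list(fit_compound = fc, sim_suspects = ss, ann_compound = ac)
    } else {
      af <- if (!is.null(spectrum)) {
        asp <- annotate_fragments(spectrum, row$formula, config)
        asp$explained_intensity_fraction
      } else NA_real_
      comp <- list(fit_formula = ff, ann_formula = af)
    }
    data.frame(group_id = feature$group_id, candidate_id = row$candidate_id,
               kind = if (compound) "compound" else "formula",
               formula = row$formula,
               smiles = if (compound) row$smiles else NA_character_,
               fit_compound = fc, sim_suspects = ss, ann_compound = ac,
               fit_formula = ff, ann_formula = af,
               tp_score = .combine_tp_score(comp),
               stringsAsFactors = FALSE)
  }
  scores <- rbind(
    if (nrow(cmp)) do.call(rbind, lapply(seq_len(nrow(cmp)), function(i)
      score_one(cmp[i, ], TRUE))),
    if (nrow(fml)) do.call(rbind, lapply(seq_len(nrow(fml)), function(i)
      score_one(fml[i, ], FALSE))))
  if (is.null(scores) || !nrow(scores)) {
    out <- data.frame()
    attr(out, "stages") <- c(stages, thresholds = 0L, top_n = 0L)
    return(out)
  }
  if (!is.null(thresholds)) {
    pass <- rep(TRUE, nrow(scores))
    for (m in names(thresholds)) {
      v <- scores[[m]]
      pass <- pass & (is.na(v) | v >= thresholds[[m]])
    }
    scores <- scores[pass, , drop = FALSE]
  }
  stages <- c(stages, thresholds = nrow(scores))
  ord <- order(-scores$tp_score, -scores$fit_formula, scores$candidate_id)
  scores <- scores[ord, , drop = FALSE]
  scores <- head(scores, config$top_n)
  scores$rank <- seq_len(nrow(scores))
  stages <- c(stages, top_n = nrow(scores))
  rownames(scores) <- NULL
  attr(scores, "stages") <- stages
  scores
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score manually proposed structures for a formula-annotated feature
#'
#' Proposals must share the feature's assigned formula (mismatches are
#' rejected by name); each proposal is then scored with the full compound
#' TP score, using the proposals as the candidate database.
#'
#' @param feature Feature row (needs `group_id`, `rt`).
#' @param proposals List of `structure_record`s (or data frame with
#'   `candidate_id`, `smiles`).
#' @param assigned_formula The feature's assigned formula.
#' @param parent Parent `structure_record`.
#' @param suspects,spectrum,config As in [rank_candidates()].
#' @return Ranked `CandidateScore` data frame; rejected proposals in
#'   attribute `rejected`.
#' @export
score_proposed_structures <- function(feature, proposals, assigned_formula,
                                      parent, suspects = NULL, spectrum = NULL,
                                      config = default_config()) {
  if (inherits(proposals, "data.frame")) {
    pl <- lapply(seq_len(nrow(proposals)), function(i)
      structure_record(proposals$candidate_id[i], proposals$smiles[i]))
  } else pl <- proposals
  if (!length(pl)) {
    out <- data.frame()
    attr(out, "rejected") <- character(0)
    return(out)
  }
  want <- mf_render(mf_parse(assigned_formula, names(.tp_isotopes)))
  ok <- vapply(pl, function(p) mf_render(p$formula) == want, logical(1))
  rejected <- vapply(pl[!ok], function(p)
    paste0(p$id, " (", mf_render(p$formula), " != ", want, ")"), character(1))
  pl <- pl[ok]
  cand <- if (length(pl)) data.frame(
    candidate_id = vapply(pl, `[[`, character(1), "id"),
    smiles = vapply(pl, `[[`, character(1), "smiles"),
    formula = vapply(pl, function(p) mf_render(p$formula), character(1)),
    stringsAsFactors = FALSE)
  else data.frame(candidate_id = character(0), smiles = character(0),
                  formula = character(0))
  out <- rank_candidates(feature, cand, parent, suspects, spectrum,
                         thresholds = NULL, config = config)
  attr(out, "rejected") <- rejected
  out
}
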