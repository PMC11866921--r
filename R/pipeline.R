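# End-to-end pipeline: prioritization -> suspect screening -> linking ->
# annotation -> unknown ranking -> identification -> semi-quantitation ->
# reporting. The state object accumulates every intermediate table so the
# report can cross-check its accounting against step provenance.

#' Assemble pipeline inputs from the packaged demo system
#'
#' @param n_noise,n_extra_formula,noise_sigma,seed Forwarded to
#'   [demo_simulation_spec()].
#' @return Input list for [run_pipeline()].
#' @export
demo_inputs <- function(n_noise = 2000L, n_extra_formula = 0L,
                        noise_sigma = 0.1, seed = 1L) {
  spec <- demo_simulation_spec(n_noise = n_noise,
                               n_extra_formula = n_extra_formula,
                               noise_sigma = noise_sigma, seed = seed)
  truth_struct <- spec$tps[!is.na(spec$tps$smiles), , drop = FALSE]
  extra <- data.frame(candidate_id = paste0("T_", truth_struct$tp_id),
                      smiles = truth_struct$smiles, stringsAsFactors = FALSE)
  list(sim_spec = spec,
       parents = spec$parents,
       suspects = demo_suspects(seed = seed),
       candidates = demo_candidate_db(extra = extra),
       standards = demo_standards(),
       library_matches = character(0))
}

.map_parent_features <- function(features, parents, config) {
  tol <- config$match_tol_mda / 1000
  out <- character(0)
  for (i in seq_len(nrow(parents))) {
    pm <- adduct_mz(mol_formula(mol_from_smiles(parents$smiles[i])),
                    config$adduct)
    hit <- which(abs(features$mz - pm) <= tol &
                   abs(features$rt - parents$rt[i]) <= 0.2)
    out[parents$parent_id[i]] <- if (length(hit))
      features$group_id[hit[which.max(rowSums(
        intensity_matrix(features)[hit, , drop = FALSE]))]] else NA_character_
  }
  out
}

#' Run the complete TP screening pipeline
#'
#' Executes every workflow stage on the supplied inputs and (optionally)
#' writes all result tables, the machine-readable summary and the HTML
#' report to `out_dir`. With a fixed seed in the simulation specification
#' the entire output is byte-identical across runs.
#'
#' @param inputs List with either `sim_spec` (a [simulation_spec()]) or
#'   pre-built `design`/`features`/`spectra`/`truth`, plus `parents`
#'   (data frame: `parent_id`, `smiles`, `rt`, `response_factor`),
#'   `suspects` (a `suspect_list`), `candidates` (candidate data frame),
#'   optional `standards` (list with `standards`, `curves`) and
#'   `library_matches` (group ids with an MS2 library hit).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param config Configuration list.
#' @return A `tp_pipeline_state` list with all intermediate and final
#'   tables.
#' @export
run_pipeline <- function(inputs, out_dir = NULL, config = default_config()) {
  state <- list(config = config)
  if (!is.null(inputs$sim_spec)) {
    sim <- simulate_experiment(inputs$sim_spec)
    state[c("design", "features", "spectra", "truth")] <- sim
  } else {
    state$design <- inputs$design
    state$features <- inputs$features
    state$spectra <- inputs$spectra %||% list()
    state$truth <- inputs$truth
  }
  state$parents <- inputs$parents
  precs <- lapply(seq_len(nrow(inputs$parents)), function(i) {
    r <- structure_record(inputs$parents$parent_id[i], inputs$parents$smiles[i])
    r$rt <- inputs$parents$rt[i]
    r
  })
  names(precs) <- inputs$parents$parent_id
  state$parent_records <- precs
  state$parent_groups <- .map_parent_features(state$features, inputs$parents,
                                              config)

  # C: prioritization
  state$prioritized <- prioritize(state$features, state$design,
                                  parent_groups = state$parent_groups,
                                  config = config)
  state$provenance <- attr(state$prioritized, "provenance")

  # D-F: suspect screening
  state$suspects <- aggregate_suspects(inputs$suspects)
  state$screen <- match_suspects(state$prioritized, state$suspects, config)
  state$unknowns <- state$screen$classes$group_id[
    state$screen$classes$class == "unknown"]

  # G: linking + pruning
  links <- build_links(state$screen$matches, state$unknowns, state$features,
                       state$design, config$detection_floor)
  state$links <- prune_links(links, state$features, state$design, config)

  # H: spectra cleanup, keyed by feature group
  cleaned <- list()
  for (sp in state$spectra) {
    g <- sp$feature_group_id
    if (is.na(g) || g %in% names(cleaned)) next
    cleaned[[g]] <- remove_background(sp, list(), config)
  }
  state$clean_spectra <- cleaned

  # calibration of ranking metrics on suspect-matched candidates
  smatch <- state$screen$matches[state$screen$matches$kind == "structure", ,
                                 drop = FALSE]
  calib <- list()
  sus_df <- as.data.frame(state$suspects)
  for (i in seq_len(nrow(smatch))) {
    srow <- sus_df[sus_df$suspect_id == smatch$suspect_id[i], ]
    feat <- state$prioritized[state$prioritized$group_id == smatch$group_id[i], ]
    p <- precs[[smatch$parent_id[i]]]
    cand <- data.frame(candidate_id = srow$suspect_id, smiles = srow$smiles,
                       formula = srow$formula, stringsAsFactors = FALSE)
    # leave-one-out: the scored suspect must not calibrate against itself
    loo <- state$suspects[state$suspects$suspect_id != srow$suspect_id, ,
                          drop = FALSE]
    sc <- rank_candidates(feat, cand, p, loo,
                          cleaned[[smatch$group_id[i]]] %||% NULL,
                          thresholds = NULL, config = config,
                          parent_rt = inputs$parents$rt[
                            inputs$parents$parent_id == smatch$parent_id[i]])
    if (nrow(sc)) calib[[length(calib) + 1L]] <- sc
  }
  state$calibration_scores <- if (length(calib)) do.call(rbind, calib) else NULL
  state$thresholds <- withCallingHandlers(
    derive_thresholds(state$calibration_scores,
                      percentile = config$threshold_percentile),
    warning = function(w) invokeRestart("muffleWarning"))

  # I-J: unknown screening (compound + formula workflows)
  kept <- state$links[state$links$status == "kept" &
                        state$links$candidate_ref == "unknown", , drop = FALSE]
  # candidate retrieval is by accurate mass: precompute database m/z
  cand_db <- inputs$candidates
  if (nrow(kept) && nrow(cand_db)) {
    cand_db$formula <- vapply(cand_db$smiles, function(s)
      tryCatch(mf_render(mol_formula(mol_from_smiles(s))),
               error = function(e) NA_character_), character(1))
    cand_db <- cand_db[!is.na(cand_db$formula), , drop = FALSE]
    cand_db$mz <- vapply(cand_db$formula, function(f)
      adduct_mz(mf_parse(f, names(.tp_isotopes)), config$adduct), numeric(1))
  }
  ranked <- list()
  for (i in seq_len(nrow(kept))) {
    g <- kept$group_id[i]; pid <- kept$parent_id[i]
    feat <- state$prioritized[state$prioritized$group_id == g, ]
    if (!nrow(feat)) next
    # formula candidates from enumeration
    fenum <- enumerate_formulas(feat$mz, config$match_tol_mda,
                                config$alphabet, config$formula_bounds)
    fcand <- if (nrow(fenum)) data.frame(
      candidate_id = paste0("F_", fenum$formula), smiles = NA_character_,
      formula = fenum$formula, stringsAsFactors = FALSE)
    else data.frame(candidate_id = character(0), smiles = character(0),
                    formula = character(0))
    hit <- abs(cand_db$mz - feat$mz) <= config$match_tol_mda / 1000
    ccand <- data.frame(candidate_id = cand_db$candidate_id[hit],
                        smiles = cand_db$smiles[hit],
                        formula = cand_db$formula[hit],
                        stringsAsFactors = FALSE)
    prt <- inputs$parents$rt[inputs$parents$parent_id == pid]
    # compound and formula workflows are ranked separately
    for (wf in c("compound", "formula")) {
      cand <- if (wf == "compound") ccand else fcand
      if (!nrow(cand)) next
      sc <- rank_candidates(feat, cand, precs[[pid]], state$suspects,
                            cleaned[[g]] %||% NULL, state$thresholds, config,
                            parent_rt = prt)
      if (nrow(sc)) {
        sc$parent_id <- pid
        sc$workflow <- wf
        sc$stage_counts <- paste(names(attr(sc, "stages")),
                                 attr(sc, "stages"), sep = "=", collapse = ";")
        ranked[[length(ranked) + 1L]] <- sc
      }
    }
  }
  state$ranked <- if (length(ranked)) do.call(rbind, ranked) else
    data.frame(group_id = character(0), candidate_id = character(0),
               kind = character(0), parent_id = character(0),
               tp_score = numeric(0), rank = integer(0))

  # K: identification levels
  state$identifications <- .assign_levels(state, inputs, config)

  # L: quantitation, removal and balances
  state$parent_quant <- .quantify_parents(state, inputs, config)
  state$removal <- .removal_table(state, inputs, config)
  state$balances <- .balance_table(state, inputs, config)

  # M: report
  state$summary <- report_summary(state)
  state$tp_reports <- report_tp_sections(state)
  class(state) <- "tp_pipeline_state"
  if (!is.null(out_dir)) write_pipeline_outputs(state, out_dir)
  state
}

#' @export
print.tp_pipeline_state <- function(x, ...) {
  cat("<tpscreen pipeline state>\n")
  cat("  features:", x$provenance[["sample_grouped"]],
      "-> prioritized:", x$provenance[["prioritized"]], "\n")
  cat("  links kept:", sum(x$links$status == "kept"),
      "| identified TPs:", nrow(x$identifications), "\n")
  invisible(x)
}

.best_candidate <- function(state, g, pid) {
  r <- state$ranked[state$ranked$group_id == g &
                      state$ranked$parent_id == pid, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  # a structure assignment beats a formula-only assignment
  cmp <- r[r$kind == "compound", , drop = FALSE]
  r <- if (nrow(cmp)) cmp else r
  r[order(r$rank), ][1, ]
}

.assign_levels <- function(state, inputs, config) {
  sus_df <- as.data.frame(state$suspects)
  std <- inputs$standards$standards
  rows <- list()
  kept <- state$links[state$links$status == "kept", , drop = FALSE]
  for (i in seq_len(nrow(kept))) {
    g <- kept$group_id[i]; pid <- kept$parent_id[i]
    ref <- kept$candidate_ref[i]
    feat <- state$prioritized[state$prioritized$group_id == g, ]
    if (!nrow(feat)) next
    is_suspect <- ref != "unknown"
    srow <- if (is_suspect) sus_df[sus_df$suspect_id == ref, ] else NULL
    best <- if (!is_suspect) .best_candidate(state, g, pid) else NULL
    formula <- if (is_suspect) srow$formula
      else if (!is.null(best)) best$formula else NA_character_
    smiles <- if (is_suspect && nrow(srow) && srow$kind[1] == "structure")
        srow$smiles
      else if (!is_suspect && !is.null(best) && best$kind == "compound")
        best$smiles
      else NA_character_
    if (!length(formula)) formula <- NA_character_
    if (!length(smiles)) smiles <- NA_character_
    formula <- formula[1]; smiles <- smiles[1]
    # reference-standard confirmation
    confirmed <- FALSE
    if (!is.null(std) && !is.na(formula)) {
      for (j in seq_len(nrow(std))) {
        if (std$formula[j] != formula) next
        cf <- confirm_with_standard(feat, std[j, ], NULL, config)
        if (cf$confirmed) { confirmed <- TRUE; break }
      }
    }
    # competing isomeric suspects: structurally distinct (by connectivity
    # key) suspects of the same formula matched to the same feature
    competing <- FALSE
    if (is_suspect && !is.na(formula)) {
      msel <- state$screen$matches$group_id == g
      msus <- sus_df[sus_df$suspect_id %in%
                       state$screen$matches$suspect_id[msel] &
                       sus_df$kind == "structure" &
                       sus_df$formula == formula, , drop = FALSE]
      if (nrow(msus) > 1)
        competing <- length(unique(inchikey_block(msus$smiles))) > 1
    }
    ann <- if (!is.null(best)) best$ann_compound else {
      cs <- state$calibration_scores
      if (!is.null(cs) && is_suspect) {
        v <- cs$ann_compound[cs$candidate_id == ref & cs$group_id == g]
        if (length(v)) v[1] else NA_real_
      } else NA_real_
    }
    nfc <- {
      fe <- enumerate_formulas(feat$mz, config$match_tol_mda,
                               config$alphabet, config$formula_bounds)
      nrow(fe)
    }
    lvl <- assign_level(list(
      standard_confirmed = confirmed,
      competing_isomers = competing,
      library_match = g %in% (inputs$library_matches %||% character(0)),
      has_structure_candidate = !is.na(smiles) && nzchar(smiles),
      ann_score = if (is.null(ann)) NA_real_ else ann,
      n_formula_candidates = nfc))
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = g, parent_id = pid, candidate_ref = ref,
      formula = formula %||% NA_character_, smiles = smiles,
      level = lvl$level, standard_confirmed = confirmed,
      competing_isomers = competing, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = character(0), parent_id = character(0),
               candidate_ref = character(0), formula = character(0),
               smiles = character(0), level = character(0),
               standard_confirmed = logical(0), competing_isomers = logical(0))
  rownames(out) <- NULL
  out
}

.quantify_parents <- function(state, inputs, config) {
  curves <- inputs$standards$curves
  im <- intensity_matrix(state$features)
  rows <- list()
  for (pid in inputs$parents$parent_id) {
    g <- state$parent_groups[[pid]]
    if (is.na(g) || is.null(curves[[pid]])) next
    f <- mol_formula(mol_from_smiles(inputs$parents$smiles[
      inputs$parents$parent_id == pid]))
    m2 <- isotope_pattern(f, 2)$abundance[3]
    for (s in state$design$sample_id) {
      resp <- im[g, s] * m2       # M+2 channel response
      conc <- tryCatch(as.numeric(quantify(resp, curves[[pid]])),
                       error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = pid, sample_id = s, conc_ugL = conc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_id = character(0), sample_id = character(0),
               conc_ugL = numeric(0))
}

.removal_table <- function(state, inputs, config) {
  pq <- state$parent_quant
  if (!nrow(pq)) return(data.frame())
  des <- as.data.frame(state$design)
  maxc <- max(apply(des[grep("^conc_", names(des))], 1, max))
  rows <- list()
  for (pid in unique(pq$parent_id)) {
    for (cond in unique(des$condition)) {
      sel <- des$type == "mixture" & des$condition == cond &
        apply(des[grep("^conc_", names(des))], 1, max) == maxc
      s0 <- des$sample_id[sel & des$exposure_h == 0]
      s2 <- des$sample_id[sel & des$exposure_h == 2]
      if (!length(s0) || !length(s2)) next
      c0 <- pq$conc_ugL[pq$parent_id == pid & pq$sample_id %in% s0]
      c2 <- pq$conc_ugL[pq$parent_id == pid & pq$sample_id %in% s2]
      if (!length(c0) || any(is.na(c0)) || any(is.na(c2))) next
      st <- removal_stats(c0, c2)
      st$parent_id <- pid; st$condition <- cond
      rows[[length(rows) + 1L]] <- st
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame()
}

.balance_table <- function(state, inputs, config) {
  des <- as.data.frame(state$design)
  im <- intensity_matrix(state$features)
  maxc <- max(apply(des[grep("^conc_", names(des))], 1, max))
  std <- inputs$standards
  kept <- state$links[state$links$status == "kept", , drop = FALSE]
  n_parents <- tapply(kept$parent_id, kept$group_id,
                      function(x) length(unique(x)))
  id <- state$identifications
  rows <- list(); balances <- list()
  for (pid in inputs$parents$parent_id) {
    prow <- inputs$parents[inputs$parents$parent_id == pid, ]
    mw <- mf_mass(mol_formula(mol_from_smiles(prow$smiles)))
    for (cond in intersect(unique(des$condition), c("U", "UH", "UHN"))) {
      sel <- des$type == "mixture" & des$condition == cond &
        apply(des[grep("^conc_", names(des))], 1, max) == maxc &
        des$exposure_h == 2
      s2 <- des$sample_id[sel]
      if (!length(s2)) next
      rem <- state$removal
      rrow <- rem[rem$parent_id == pid & rem$condition == cond, , drop = FALSE]
      removed_uM <- if (nrow(rrow) && isTRUE(rrow$significant[1]))
        (maxc / mw) * rrow$removal_pct[1] / 100 else NA_real_
      ids <- id[id$parent_id == pid & !is.na(id$formula), , drop = FALSE]
      ids <- ids[!duplicated(ids$group_id), , drop = FALSE]  # one count per feature
      tpc <- list()
      for (j in seq_len(nrow(ids))) {
        g <- ids$group_id[j]
        if (!g %in% rownames(im)) next
        resp <- mean(im[g, s2])
        if (resp <= 0) next
        curve <- NULL
        if (!is.null(std)) {
          hit <- std$standards$analyte_id[std$standards$formula == ids$formula[j]]
          if (length(hit) && !hit[1] %in% inputs$parents$parent_id)
            curve <- std$curves[[hit[1]]]
        }
        q <- tryCatch(semi_quantify(resp, ids$formula[j], curve = curve,
                                    rf_predicted = prow$response_factor,
                                    config = config),
                      error = function(e) NULL)
        if (is.null(q)) next
        tpc[[length(tpc) + 1L]] <- data.frame(
          tp_id = paste0(g, "/", ids$candidate_ref[j]), conc_uM = q$conc_uM,
          provenance = q$provenance,
          n_parents = if (g %in% names(n_parents))
            as.integer(n_parents[[g]]) else 1L,
          stringsAsFactors = FALSE)
      }
      tpc <- if (length(tpc)) do.call(rbind, tpc) else
        data.frame(tp_id = character(0), conc_uM = numeric(0),
                   provenance = character(0))
      mb <- mass_balance(removed_uM, tpc, parent_id = pid, condition = cond)
      balances[[length(balances) + 1L]] <- mb
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = pid, condition = cond,
        parent_removed_uM = removed_uM,
        explained_pct = mb$explained_fraction,
        n_tps = nrow(tpc), defined = mb$defined, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "balances") <- balances
  out
}
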