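# Reporting: TP identifiers, workflow accounting (overview and candidate-
# prioritization tables), per-TP report sections, and the output writers
# (CSV tables, JSON summary, self-contained HTML).

#' Build a TP identifier
#'
#' Identifier scheme `<Class>-<PARENT>-M<nominal [M+H]+>-<index>`, e.g.
#' `SuS-SMX-M94-1`. Classes: `SuS` (structure suspect), `SuF` (formula
#' suspect), `UnC` (unknown, compound workflow), `UnF` (unknown, formula
#' workflow).
#'
#' @param class One of `SuS`, `SuF`, `UnC`, `UnF`.
#' @param parent_id Parent identifier.
#' @param mz Feature m/z (`[M+H]+`).
#' @param index Running index within the class/parent/nominal-mass group.
#' @return Identifier string.
#' @export
tp_identifier <- function(class, parent_id, mz, index) {
  stopifnot(class %in% c("SuS", "SuF", "UnC", "UnF"))
  paste0(class, "-", parent_id, "-M", round(mz), "-", index)
}

.link_class <- function(state, ref, g, pid) {
  if (ref != "unknown") {
    sus <- as.data.frame(state$suspects)
    k <- sus$kind[sus$suspect_id == ref]
    if (length(k) && k[1] == "structure") "SuS" else "SuF"
  } else {
    best <- .best_candidate(state, g, pid)
    if (!is.null(best) && best$kind == "compound") "UnC" else "UnF"
  }
}

#' Workflow accounting tables
#'
#' Builds the overview accounting (per-parent and total counts for every
#' workflow step) and verifies it against the prioritization provenance
#' and the feature classification -- an inconsistency is a hard failure,
#' because it means the bookkeeping itself is broken.
#'
#' @param state A `tp_pipeline_state`.
#' @return List with `overview` (data frame) and `totals` (named list).
#' @export
report_summary <- function(state) {
  cls <- state$screen$classes
  n_prior <- nrow(state$prioritized)
  n_struct <- sum(cls$class == "structure")
  n_form <- sum(cls$class == "formula")
  n_unknown <- sum(cls$class == "unknown")
  if (n_struct + n_form + n_unknown != n_prior)
    stop("accounting inconsistency: feature classes do not partition the ",
         "prioritized set")
  if (n_prior != unname(state$provenance[["prioritized"]]))
    stop("accounting inconsistency: prioritized count does not match ",
         "provenance")
  acct <- state$screen$accounting
  kept <- state$links[state$links$status == "kept", , drop = FALSE]
  per_parent <- do.call(rbind, lapply(acct$parent_id, function(p) {
    a <- acct[acct$parent_id == p, ]
    data.frame(
      parent_id = p,
      total_structure_suspects = a$total_structure_suspects,
      matched_structure_suspects = a$matched_structure_suspects,
      total_formula_suspects = a$total_formula_suspects,
      matched_formula_suspects = a$matched_formula_suspects,
      matched_features = a$matched_features,
      suspect_links = sum(kept$parent_id == p & kept$candidate_ref != "unknown"),
      unknown_links = sum(kept$parent_id == p & kept$candidate_ref == "unknown"))
  }))
  totals <- list(
    features_grouped = unname(state$provenance[["sample_grouped"]]),
    features_prioritized = n_prior,
    structure_matched_features = n_struct,
    formula_matched_features = n_form,
    total_matched_features = n_struct + n_form,
    unknown_features = n_unknown,
    total_links = nrow(kept),
    suspect_links = sum(kept$candidate_ref != "unknown"),
    unknown_links = sum(kept$candidate_ref == "unknown"),
    identified_tps = nrow(state$identifications),
    levels = as.list(table(state$identifications$level)))
  if (totals$total_matched_features !=
        totals$structure_matched_features + totals$formula_matched_features)
    stop("accounting inconsistency: matched-feature totals")
  if (totals$unknown_features != n_prior - totals$total_matched_features)
    stop("accounting inconsistency: unknown features must be the ",
         "prioritized minus matched count")
  list(overview = per_parent, totals = totals)
}

#' Per-TP report sections
#'
#' One section per identified TP candidate: identifier, formula/structure,
#' identification level, scores, condition-presence flags (U/UH/UHN and
#' S for single-parent experiments), and the abundance-versus-initial-
#' concentration table.
#'
#' @param state A `tp_pipeline_state`.
#' @return Data frame of report rows (one per TP candidate).
#' @export
report_tp_sections <- function(state) {
  id <- state$identifications
  if (!nrow(id)) return(data.frame())
  des <- as.data.frame(state$design)
  im <- intensity_matrix(state$features)
  floor_ <- state$config$detection_floor
  rows <- list()
  counter <- new.env()
  for (i in seq_len(nrow(id))) {
    g <- id$group_id[i]; pid <- id$parent_id[i]
    feat <- state$prioritized[state$prioritized$group_id == g, ]
    if (!nrow(feat)) next
    cl <- .link_class(state, id$candidate_ref[i], g, pid)
    key <- paste(cl, pid, round(feat$mz))
    idx <- (if (exists(key, counter)) get(key, counter) else 0L) + 1L
    assign(key, idx, counter)
    ident <- tp_identifier(cl, pid, feat$mz, idx)
    pres <- vapply(c("U", "UH", "UHN"), function(cc) {
      s <- des$sample_id[des$type == "mixture" & des$condition == cc &
                           des$exposure_h == 2]
      length(s) > 0 && any(im[g, s] > floor_)
    }, logical(1))
    ssamp <- des$sample_id[grepl("^single:", des$type) & des$exposure_h == 2]
    pres_s <- length(ssamp) > 0 && any(im[g, ssamp] > floor_)
    mix2 <- des[des$type == "mixture" & des$exposure_h == 2 &
                  des$condition %in% c("U", "UH", "UHN"), ]
    conc <- apply(mix2[grep("^conc_", names(mix2))], 1, max)
    ab <- tapply(im[g, mix2$sample_id], conc, mean)
    reg <- attr(state$prioritized, "regression")
    rr <- reg[reg$group_id == g, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      tp_identifier = ident, group_id = g, parent_id = pid,
      candidate_ref = id$candidate_ref[i], class = cl,
      formula = id$formula[i], smiles = id$smiles[i], level = id$level[i],
      mz = feat$mz, rt = feat$rt,
      present_U = pres[["U"]], present_UH = pres[["UH"]],
      present_UHN = pres[["UHN"]], present_single = pres_s,
      abundance_by_conc = paste(names(ab), round(unname(ab), 1),
                                sep = ":", collapse = ";"),
      r_squared = if (nrow(rr)) rr$r_squared else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write all pipeline outputs
#'
#' Writes the result tables (CSV), the machine-readable summary (JSON),
#' the run log (the effective configuration) and a self-contained HTML
#' report into `out_dir`. Output is deterministic: no timestamps, fixed
#' ordering and number formatting.
#'
#' @param state A `tp_pipeline_state`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(state, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_run_log(state$config, p("run_log.txt"))
  write_design(state$design, p("design.csv"))
  write_features(state$prioritized, p("features_prioritized.csv"))
  write_suspects(state$suspects, p("suspects_aggregated.csv"))
  write.csv(state$screen$matches, p("suspect_matches.csv"), row.names = FALSE)
  write.csv(state$links, p("links.csv"), row.names = FALSE)
  write.csv(state$ranked, p("candidates_ranked.csv"), row.names = FALSE)
  write.csv(state$identifications, p("identifications.csv"), row.names = FALSE)
  if (nrow(state$balances))
    write.csv(as.data.frame(state$balances), p("mass_balances.csv"),
              row.names = FALSE)
  if (nrow(state$removal))
    write.csv(state$removal, p("parent_removal.csv"), row.names = FALSE)
  if (nrow(state$tp_reports))
    write.csv(state$tp_reports, p("tp_report.csv"), row.names = FALSE)
  summary_out <- list(
    provenance = as.list(state$provenance),
    totals = state$summary$totals,
    overview = state$summary$overview,
    thresholds = state$thresholds)
  jsonlite::write_json(summary_out, p("summary.json"), auto_unbox = TRUE,
                       digits = 8, pretty = TRUE)
  writeLines(render_report_html(state), p("report.html"))
  invisible(out_dir)
}

#' Render the HTML report
#'
#' Self-contained single-file HTML: overview accounting, per-TP sections
#' and mass balances. No external assets.
#'
#' @param state A `tp_pipeline_state`.
#' @return Character vector of HTML lines.
#' @export
render_report_html <- function(state) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  tab <- function(df) {
    if (is.null(df) || !nrow(df)) return("<p><em>none</em></p>")
    c("<table border='1' cellspacing='0' cellpadding='3'>",
      paste0("<tr>", paste0("<th>", esc(names(df)), "</th>", collapse = ""),
             "</tr>"),
      vapply(seq_len(nrow(df)), function(i)
        paste0("<tr>", paste0("<td>",
                              esc(vapply(df[i, ], function(v)
                                if (is.numeric(v)) format(signif(v, 6)) else
                                  as.character(v), character(1))),
                              "</td>", collapse = ""), "</tr>"),
        character(1)),
      "</table>")
  }
  tot <- state$summary$totals
  c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>TP screening report</title></head><body>",
    "<h1>Transformation-product screening report</h1>",
    "<h2>Workflow overview</h2>",
    paste0("<p>Features grouped: ", tot$features_grouped,
           "; prioritized: ", tot$features_prioritized,
           "; matched to suspects: ", tot$total_matched_features,
           "; unknowns: ", tot$unknown_features,
           "; parent/TP links kept: ", tot$total_links, ".</p>"),
    tab(state$summary$overview),
    "<h2>Identified TP candidates</h2>",
    tab(state$tp_reports),
    "<h2>Parent removal</h2>",
    tab(state$removal),
    "<h2>Semi-quantitative molar mass balances</h2>",
    tab(if (nrow(state$balances)) as.data.frame(state$balances) else NULL),
    "</body></html>")
}
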