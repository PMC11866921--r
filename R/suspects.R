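# Suspect TP screening: aggregation of multi-source suspect lists,
# metabolic-logic formula suspects, and accurate-m/z matching against
# prioritized features.

#' Default metabolic-logic transformation deltas
#'
#' Formula deltas applied to a parent to generate formula suspects:
#' oxidations, hydrations, (de)hydrogenations, peroxide addition,
#' demethylation and the trifluoroethyl loss typical of the studied
#' chemistry. Each delta is a list with `add` and/or `sub` formula strings
#' and a `label`.
#'
#' @return List of deltas.
#' @export
metabolic_deltas <- function() {
  list(
    list(add = "O", sub = NULL, label = "+O"),
    list(add = "O2", sub = NULL, label = "+2O"),
    list(add = "O", sub = "H2", label = "-H2+O"),
    list(add = "H2O", sub = NULL, label = "+H2O"),
    list(add = NULL, sub = "H2", label = "-H2"),
    list(add = "H2", sub = NULL, label = "+H2"),
    list(add = "H2O2", sub = NULL, label = "+H2O2"),
    list(add = NULL, sub = "CH2", label = "-CH2"),
    list(add = NULL, sub = "C2HF3", label = "-C2HF3"))
}

apply_delta <- function(f, delta) {
  out <- mf_parse(f, names(.tp_isotopes))
  if (!is.null(delta$sub)) out <- mf_subtract(out, delta$sub)
  if (!is.null(delta$add)) out <- mf_add(out, delta$add)
  out
}

#' Generate formula suspects by metabolic logic
#'
#' Applies each delta to the parent formula; infeasible deltas (counts
#' would go negative) are skipped with a logged reason.
#'
#' @param parent A `structure_record` (or a list with `id` and `formula`).
#' @param deltas List of deltas, see [metabolic_deltas()].
#' @return A `suspect_list` of `kind = "formula"` suspects with source tag
#'   `LOGIC`; skipped deltas in attribute `skipped`.
#' @export
logic_formula_suspects <- function(parent, deltas = metabolic_deltas()) {
  rows <- list(); skipped <- character(0)
  for (d in deltas) {
    f <- tryCatch(apply_delta(parent$formula, d), error = function(e) e)
    if (inherits(f, "error")) {
      skipped <- c(skipped, paste0(d$label, ": ", conditionMessage(f)))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      suspect_id = paste0("LOGIC_", parent$id, "_",
                          gsub("\\+", "p", gsub("-", "m", d$label))),
      parent_id = parent$id, kind = "formula", smiles = NA_character_,
      formula = mf_render(f), sources = "LOGIC", label = d$label,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) suspect_list(do.call(rbind, rows)) else
    suspect_list(data.frame(suspect_id = character(0), parent_id = character(0),
                            kind = character(0)))
  attr(out, "skipped") <- skipped
  out
}

#' Aggregate multi-source suspect lists
#'
#' Deduplicates suspects: structure suspects by parent and connectivity
#' key (first InChI-key block, so stereoisomers merge), formula suspects
#' by parent and formula. Source tags are unioned; per-source and overlap
#' counts are attached as attribute `source_counts`.
#'
#' @param suspects A `suspect_list` or list of them (e.g. one per source).
#' @return Deduplicated `suspect_list`.
#' @export
aggregate_suspects <- function(suspects) {
  if (inherits(suspects, "suspect_list")) suspects <- list(suspects)
  all <- do.call(rbind, lapply(suspects, as.data.frame))
  if (is.null(all) || !nrow(all))
    return(suspect_list(data.frame(suspect_id = character(0),
                                   parent_id = character(0),
                                   kind = character(0))))
  key <- character(nrow(all))
  is_s <- all$kind == "structure"
  key[is_s] <- paste0(all$parent_id[is_s], "|S|", inchikey_block(all$smiles[is_s]))
  key[!is_s] <- paste0(all$parent_id[!is_s], "|F|", all$formula[!is_s])
  keep <- !duplicated(key)
  out <- all[keep, , drop = FALSE]
  srcs <- function(x) sort(unique(unlist(strsplit(x, ";"))))
  out$sources <- vapply(key[keep], function(k)
    paste(srcs(paste(all$sources[key == k], collapse = ";")), collapse = ";"),
    character(1), USE.NAMES = FALSE)
  rownames(out) <- NULL
  res <- suspect_list(out)
  tags <- srcs(paste(res$sources, collapse = ";"))
  counts <- vapply(tags, function(t)
    sum(vapply(strsplit(res$sources, ";"), function(s) t %in% s, logical(1))),
    integer(1))
  unique_counts <- vapply(tags, function(t) sum(res$sources == t), integer(1))
  attr(res, "source_counts") <- data.frame(source = tags, n = counts,
                                           n_unique = unique_counts)
  res
}

#' Match suspects to prioritized features by accurate m/z
#'
#' A feature matches a suspect when the absolute difference between the
#' feature m/z and the suspect's adduct m/z is within `match_tol_mda`.
#' Structure suspects claim features first; formula suspects are only
#' attempted on structure-unmatched features; the remainder is labeled
#' `unknown`. Every prioritized feature lands in exactly one class.
#'
#' @param features Prioritized `feature_table`.
#' @param suspects Aggregated `suspect_list`.
#' @param config Configuration (uses `match_tol_mda`, `adduct`).
#' @return List with `matches` (feature/suspect pairs and m/z errors),
#'   `classes` (one row per feature with its class) and `accounting`
#'   (per-parent match counts).
#' @export
match_suspects <- function(features, suspects, config = default_config()) {
  tol <- config$match_tol_mda / 1000
  sus <- as.data.frame(suspects)
  sus$mz <- vapply(sus$formula, function(f)
    adduct_mz(mf_parse(f, names(.tp_isotopes)), config$adduct), numeric(1))
  cls <- rep("unknown", nrow(features))
  names(cls) <- features$group_id
  matches <- list()
  for (kind in c("structure", "formula")) {
    sk <- sus[sus$kind == kind, , drop = FALSE]
    for (i in seq_len(nrow(features))) {
      if (kind == "formula" && cls[i] == "structure") next
      d <- abs(sk$mz - features$mz[i])
      hit <- which(d <= tol)
      if (length(hit)) {
        cls[i] <- kind
        matches[[length(matches) + 1L]] <- data.frame(
          group_id = features$group_id[i], suspect_id = sk$suspect_id[hit],
          parent_id = sk$parent_id[hit], kind = kind,
          mz_error_mda = (features$mz[i] - sk$mz[hit]) * 1000,
          stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(group_id = character(0), suspect_id = character(0),
               parent_id = character(0), kind = character(0),
               mz_error_mda = numeric(0))
  classes <- data.frame(group_id = features$group_id, class = unname(cls),
                        stringsAsFactors = FALSE)
  acct <- do.call(rbind, lapply(sort(unique(sus$parent_id)), function(p) {
    m <- matches[matches$parent_id == p, , drop = FALSE]
    data.frame(parent_id = p,
               total_structure_suspects = sum(sus$kind == "structure" & sus$parent_id == p),
               matched_structure_suspects = length(unique(m$suspect_id[m$kind == "structure"])),
               total_formula_suspects = sum(sus$kind == "formula" & sus$parent_id == p),
               matched_formula_suspects = length(unique(m$suspect_id[m$kind == "formula"])),
               matched_features = length(unique(m$group_id)))
  }))
  list(matches = matches, classes = classes, accounting = acct)
}
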