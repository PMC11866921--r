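# Parent-TP linking: suspect-matched features link to their suspect's
# parent; unknown features provisionally link to every parent present in
# the mixtures, and links are pruned with single-parent-experiment
# evidence.

#' Build provisional parent-TP links
#'
#' Suspect-matched features produce one link per (parent, suspect);
#' unknown features link to every parent whose mixture samples contain the
#' feature above the detection floor (these are pruned later).
#'
#' @param matches Match table from [match_suspects()] (`$matches`).
#' @param unknowns Character vector of unknown feature group ids.
#' @param features `feature_table` with intensities.
#' @param design `experiment_design`.
#' @param detection_floor Intensity at or below which a feature counts as
#'   absent.
#' @return Data frame of `TPLink` rows: `parent_id`, `group_id`,
#'   `candidate_ref`, `status`.
#' @export
build_links <- function(matches, unknowns, features, design,
                        detection_floor = 0) {
  rows <- list()
  if (nrow(matches))
    for (i in seq_len(nrow(matches)))
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = matches$parent_id[i], group_id = matches$group_id[i],
        candidate_ref = matches$suspect_id[i], status = "kept",
        stringsAsFactors = FALSE)
  if (length(unknowns)) {
    im <- intensity_matrix(features)
    mix2 <- design[design$type == "mixture" & design$exposure_h == 2, ,
                   drop = FALSE]
    parents <- design_parents(design)
    for (g in unknowns) {
      if (!g %in% rownames(im)) next
      present <- any(im[g, mix2$sample_id] > detection_floor)
      if (!present) next
      for (p in parents)
        rows[[length(rows) + 1L]] <- data.frame(
          parent_id = p, group_id = g, candidate_ref = "unknown",
          status = "kept", stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent_id = character(0), group_id = character(0),
               candidate_ref = character(0), status = character(0))
  if (anyDuplicated(out[c("parent_id", "group_id", "candidate_ref")]))
    out <- out[!duplicated(out[c("parent_id", "group_id", "candidate_ref")]), ]
  rownames(out) <- NULL
  out
}

#' Prune links using single-parent experiments
#'
#' A link (parent P, feature F) is removed when F is present in the
#' single-parent experiments of any other parent Q, unless the mixture
#' intensity is at least `link_intensity_factor` times the intensity in
#' Q's single-parent run, or F is also present in P's own single-parent
#' run. Presence means intensity above the detection floor; intensities
#' are the maximum across replicates at the highest shared concentration
#' (single-parent runs are performed at the top level only).
#'
#' @param links Link table from [build_links()].
#' @param features `feature_table`.
#' @param design `experiment_design`.
#' @param config Configuration (uses `link_intensity_factor`,
#'   `detection_floor`).
#' @return Link table with `status` set to `kept` or `removed:<reason>`.
#' @export
prune_links <- function(links, features, design, config = default_config()) {
  if (!nrow(links)) return(links)
  im <- intensity_matrix(features)
  floor_ <- config$detection_floor
  k <- config$link_intensity_factor
  maxc <- max(apply(design[grep("^conc_", names(design))], 1, max))
  mix2 <- design[design$type == "mixture" & design$exposure_h == 2 &
                   design$condition %in% c("U", "UH", "UHN") &
                   apply(design[grep("^conc_", names(design))], 1, max) == maxc, ,
                 drop = FALSE]
  single2 <- function(p) design[design$type == paste0("single:", p) &
                                  design$exposure_h == 2, , drop = FALSE]
  parents <- design_parents(design)
  for (i in seq_len(nrow(links))) {
    g <- links$group_id[i]; p <- links$parent_id[i]
    if (!g %in% rownames(im)) next
    mix_int <- max(im[g, mix2$sample_id], 0)
    own <- single2(p)
    own_present <- nrow(own) > 0 && any(im[g, own$sample_id] > floor_)
    for (q in setdiff(parents, p)) {
      sq <- single2(q)
      if (!nrow(sq)) next
      q_int <- max(im[g, sq$sample_id], 0)
      if (q_int > floor_) {
        if (own_present) next                       # own-parent clause
        if (mix_int >= k * q_int) next              # intensity-ratio clause
        links$status[i] <- paste0("removed:present in single-parent ", q)
        break
      }
    }
  }
  links
}
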