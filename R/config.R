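# Workflow configuration: every threshold used by the pipeline lives here,
# with defaults mirroring the screening conditions the package targets.
# m/z tolerances are absolute mDa; retention times are minutes.

#' Default workflow configuration
#'
#' Returns the full configuration list with every tunable threshold of the
#' screening workflow. Values can be overridden via [read_config()] or by
#' passing a modified list to the pipeline functions.
#'
#' Key groups:
#' \describe{
#'   \item{alphabet, adduct}{Element alphabet for formulas; ionization
#'     adduct (positive electrospray, `[M+H]+`).}
#'   \item{blank_factor, min_intensity, min_replicates, min_conc_levels,
#'     alpha, r2_relaxed}{Prioritization: 0 h blank-subtraction factor,
#'     intensity floor, replicate-detection minimum, minimum concentration
#'     arms with detection, one-sided regression significance level and the
#'     relaxed R-squared branch that tolerates saturation-flattened trends.}
#'   \item{match_tol_mda}{Suspect-screening accurate-m/z tolerance (mDa).}
#'   \item{link_intensity_factor, detection_floor}{Parent-TP link pruning:
#'     mixture/single-parent intensity ratio and the detection floor.}
#'   \item{background_factor, rel_int_floor, frag_tol_mda, frag_depth,
#'     frag_h_tolerance, precursor_window_mz}{MS2 cleanup and annotation.}
#'   \item{formula_bounds}{Element-count bounds for formula enumeration.}
#'   \item{forbidden_elements, tol_logp, top_n, threshold_percentile,
#'     fit_direction, mcs_time_budget_s}{Unknown-candidate filtering and
#'     ranking.}
#'   \item{rt_tol_min, mz_tol_mda, msigma_max}{Reference-standard
#'     confirmation tolerances.}
#'   \item{rf_uncertainty_factor}{Uncertainty band for predicted response
#'     factors.}
#' }
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    alphabet = c("C", "H", "N", "O", "S", "F"),
    adduct = "[M+H]+",
    # prioritization
    blank_factor = 5,
    min_intensity = 1000,
    min_replicates = 2,
    min_conc_levels = 2,
    alpha = 0.05,
    r2_relaxed = 0.7,
    # suspect screening
    match_tol_mda = 5,
    # parent/TP linking
    link_intensity_factor = 5,
    detection_floor = 0,
    # MS2 cleanup + annotation
    background_factor = 2,
    rel_int_floor = 0.01,
    frag_tol_mda = 5,
    frag_depth = 2,
    frag_h_tolerance = 1,
    precursor_window_mz = 0.5,
    formula_bounds = c(C = 20, H = 40, N = 5, O = 8, S = 2, F = 6),
    # unknown-candidate ranking
    forbidden_elements = c("Cl", "Br", "Si", "P"),
    tol_logp = 2,
    top_n = 25,
    threshold_percentile = 5,
    fit_direction = "max",
    mcs_time_budget_s = 2,
    ann_component = "score",
    # identification / quantitation
    rt_tol_min = 0.1,
    mz_tol_mda = 5,
    msigma_max = 100,
    rf_uncertainty_factor = 5,
    seed = 1L
  )
}

#' Read a workflow configuration file
#'
#' Reads a YAML configuration and merges it over the defaults. Unknown keys
#' are an error (they usually indicate a typo in a threshold name).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional named list applied after the file.
#' @return Full configuration list.
#' @export
read_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  apply_over <- function(cfg, ov, origin) {
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop("unknown config key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "))
    for (k in names(ov)) {
      v <- ov[[k]]
      if (k == "formula_bounds" && !is.null(names(v))) v <- unlist(v)
      cfg[[k]] <- v
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  if (!is.null(overrides)) cfg <- apply_over(cfg, overrides, "overrides")
  cfg
}

#' Write the effective configuration to a run log
#'
#' Echoes every configuration value into a plain-text run log so each run
#' records its full provenance.
#'
#' @param config Configuration list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(config, path) {
  lines <- c("# tpscreen run configuration",
             yaml::as.yaml(config))
  writeLines(lines, path)
  invisible(path)
}
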