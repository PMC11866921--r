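# Readers, writers and validation for the workflow's tabular formats:
# experiment designs, feature-group tables, suspect lists, MS2 spectra
# (MSP text, optionally mzML through mzR), reference standards and
# candidate tables. All readers validate fully and fail with named errors;
# they never return partial objects.

# ---- experiment design -----------------------------------------------------

#' Construct and validate an experiment design
#'
#' A design maps samples to their role in the degradation experiment:
#' `type` (`mixture`, `single:<parent>`, `blank`, `standard`), `condition`
#' (`U`, `UH`, `UHN` and dark variants `D`, `DH`, `DHN`), `exposure_h`
#' (0 or 2), `replicate`, and one `conc_<parent>` column per parent with
#' the initial concentration in ug/L.
#'
#' Invariants checked: unique sample ids; every 2 h sample has at least one
#' 0 h partner with the same type/condition/concentrations; replicate >= 1.
#'
#' @param df Data frame with the columns above.
#' @return An `experiment_design`.
#' @export
experiment_design <- function(df) {
  req <- c("sample_id", "type", "condition", "exposure_h", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("design is missing column(s): ", paste(miss, collapse = ", "))
  cc <- grep("^conc_", names(df), value = TRUE)
  if (!length(cc)) stop("design is missing per-parent conc_<parent> columns")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  okt <- df$type %in% c("mixture", "blank", "standard") | grepl("^single:", df$type)
  if (any(!okt)) stop("invalid sample type: ", paste(df$type[!okt], collapse = ", "))
  okc <- df$condition %in% c("U", "UH", "UHN", "D", "DH", "DHN", "none")
  if (any(!okc)) stop("invalid condition: ", paste(df$condition[!okc], collapse = ", "))
  if (!all(df$exposure_h %in% c(0, 2)))
    stop("exposure_h must be 0 or 2")
  if (any(df$replicate < 1)) stop("replicate must be >= 1")
  key <- function(d) paste(d$type, d$condition, do.call(paste, d[cc]))
  two <- df[df$exposure_h == 2, , drop = FALSE]
  zero <- df[df$exposure_h == 0, , drop = FALSE]
  unmatched <- !(key(two) %in% key(zero))
  if (any(unmatched))
    stop("2 h sample(s) without a matching 0 h partner: ",
         paste(two$sample_id[unmatched], collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  structure(df, class = c("experiment_design", "data.frame"),
            parents = sub("^conc_", "", cc))
}

design_parents <- function(design) attr(design, "parents")

#' @rdname experiment_design
#' @param path CSV file path.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  experiment_design(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE))
}

#' @rdname experiment_design
#' @param design An `experiment_design`.
#' @export
write_design <- function(design, path) {
  write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- feature-group table ---------------------------------------------------

#' Construct and validate a feature-group table
#'
#' Aligned LC-HRMS feature groups: one row per group with `group_id`, `mz`,
#' `rt` (minutes) and one intensity column per sample (wide layout; zero
#' means not detected).
#'
#' @param df Wide data frame as above.
#' @param design Optional `experiment_design`; when given, intensity
#'   columns must exactly match its sample ids.
#' @return A `feature_table`.
#' @export
feature_table <- function(df, design = NULL) {
  req <- c("group_id", "mz", "rt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$group_id))
    stop("duplicate group_id: ",
         paste(unique(df$group_id[duplicated(df$group_id)]), collapse = ", "))
  if (any(df$mz <= 0)) stop("feature m/z must be positive")
  if (any(df$rt < 0)) stop("feature retention time must be non-negative")
  samples <- setdiff(names(df), req)
  if (!is.null(design)) {
    extra <- setdiff(samples, design$sample_id)
    if (length(extra))
      stop("intensity column(s) for unknown sample(s): ",
           paste(extra, collapse = ", "))
    missing_s <- setdiff(design$sample_id, samples)
    if (length(missing_s))
      stop("design sample(s) missing from feature table: ",
           paste(missing_s, collapse = ", "))
    samples <- design$sample_id
    df <- df[, c(req, samples)]
  }
  if (nrow(df) && any(as.matrix(df[samples]) < 0, na.rm = TRUE))
    stop("negative intensities in feature table")
  structure(df, class = c("feature_table", "data.frame"), samples = samples)
}

feature_samples <- function(ft) attr(ft, "samples")

intensity_matrix <- function(ft) {
  m <- as.matrix(as.data.frame(ft)[, feature_samples(ft), drop = FALSE])
  rownames(m) <- ft$group_id
  m
}

#' @rdname feature_table
#' @param path CSV file path.
#' @export
read_features <- function(path, design = NULL) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  feature_table(read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                design)
}

#' Read a long-format feature table
#'
#' Interoperability reader for long CSVs with columns `group_id`, `mz`,
#' `rt`, `sample_id`, `intensity`; missing combinations become zero.
#'
#' @param path CSV file path.
#' @param design Optional design for validation.
#' @return A `feature_table` (wide).
#' @export
read_features_long <- function(path, design = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("group_id", "mz", "rt", "sample_id", "intensity")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("long feature table missing column(s): ",
                         paste(miss, collapse = ", "))
  wide <- stats::reshape(d, idvar = c("group_id", "mz", "rt"),
                         timevar = "sample_id", direction = "wide")
  names(wide) <- sub("^intensity\\.", "", names(wide))
  wide[is.na(wide)] <- 0
  feature_table(wide, design)
}

#' @rdname feature_table
#' @export
write_features <- function(ft, path) {
  write.csv(as.data.frame(ft), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- suspects --------------------------------------------------------------

#' Construct and validate a suspect list
#'
#' TP suspects are hypotheses tied to a parent: either a full structure
#' (`kind = "structure"`, with SMILES) or a molecular formula only
#' (`kind = "formula"`). Structure suspects must have a parseable SMILES
#' whose formula matches the `formula` column when both are given; formula
#' suspects must have no SMILES.
#'
#' @param df Data frame with columns `suspect_id`, `parent_id`, `kind`,
#'   `smiles`, `formula`, `sources` (semicolon-separated tags), `label`.
#' @return A `suspect_list` data frame with normalized formulas.
#' @export
suspect_list <- function(df) {
  req <- c("suspect_id", "parent_id", "kind")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("suspect table missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(df)
  if (!"smiles" %in% names(df)) df$smiles <- rep(NA_character_, n)
  if (!"formula" %in% names(df)) df$formula <- rep(NA_character_, n)
  if (!"sources" %in% names(df)) df$sources <- rep("", n)
  if (!"label" %in% names(df)) df$label <- rep("", n)
  df$smiles[!is.na(df$smiles) & !nzchar(df$smiles)] <- NA_character_
  df$formula[!is.na(df$formula) & !nzchar(df$formula)] <- NA_character_
  if (anyDuplicated(df$suspect_id))
    stop("duplicate suspect_id: ",
         paste(unique(df$suspect_id[duplicated(df$suspect_id)]), collapse = ", "))
  bad <- !df$kind %in% c("structure", "formula")
  if (any(bad)) stop("invalid suspect kind for: ",
                     paste(df$suspect_id[bad], collapse = ", "))
  for (i in seq_len(nrow(df))) {
    if (df$kind[i] == "structure") {
      if (is.na(df$smiles[i]))
        stop("structure suspect without SMILES: ", df$suspect_id[i])
      f <- tryCatch(mol_formula(mol_from_smiles(df$smiles[i])),
                    error = function(e)
                      stop("suspect ", df$suspect_id[i], ": ",
                           conditionMessage(e), call. = FALSE))
      if (!is.na(df$formula[i]) &&
          mf_render(f) != mf_render(mf_parse(df$formula[i], names(.tp_isotopes))))
        stop("suspect ", df$suspect_id[i], ": SMILES formula ", mf_render(f),
             " does not match declared formula ", df$formula[i])
      df$formula[i] <- mf_render(f)
    } else {
      if (!is.na(df$smiles[i]))
        stop("formula suspect must not carry a SMILES: ", df$suspect_id[i])
      if (is.na(df$formula[i]))
        stop("formula suspect without formula: ", df$suspect_id[i])
      df$formula[i] <- mf_render(mf_parse(df$formula[i], names(.tp_isotopes)))
    }
  }
  structure(df, class = c("suspect_list", "data.frame"))
}

#' @rdname suspect_list
#' @param path CSV file path.
#' @export
read_suspects <- function(path) {
  if (!file.exists(path)) stop("suspect file not found: ", path)
  suspect_list(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname suspect_list
#' @export
write_suspects <- function(suspects, path) {
  write.csv(as.data.frame(suspects), path, row.names = FALSE)
  invisible(path)
}

# ---- MS2 spectra -----------------------------------------------------------

#' Construct an MS2 spectrum
#'
#' @param feature_group_id Feature group the spectrum belongs to (may be
#'   `NA` before mapping).
#' @param precursor_mz Precursor m/z.
#' @param peaks Two-column matrix (mz, intensity), ascending mz, positive
#'   intensities.
#' @return An `ms2_spectrum`.
#' @export
ms2_spectrum <- function(feature_group_id, precursor_mz, peaks) {
  peaks <- matrix(as.numeric(peaks), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  if (nrow(peaks)) {
    if (any(peaks[, 2] <= 0)) stop("spectrum intensities must be positive")
    if (is.unsorted(peaks[, 1], strictly = FALSE))
      peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  }
  structure(list(feature_group_id = feature_group_id,
                 precursor_mz = precursor_mz, peaks = peaks),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<MS2> feature ", x$feature_group_id, ", precursor ",
      round(x$precursor_mz, 4), ", ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Read MS2 spectra
#'
#' Reads MSP-style text spectra (`NAME`/`PRECURSORMZ`/`Num Peaks` blocks)
#' or, when the extension is `.mzML`, centroided MS2 spectra through mzR
#' (precursor m/z and peak arrays only). mzML spectra are mapped to feature
#' groups by precursor m/z and retention-time window.
#'
#' @param path Spectrum file.
#' @param features Optional `feature_table` for precursor-to-feature
#'   mapping (mzML) or validation (MSP).
#' @param config Configuration (for `precursor_window_mz`).
#' @return List of `ms2_spectrum` objects.
#' @export
read_spectra <- function(path, features = NULL, config = default_config()) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "msp") read_spectra_msp(path)
  else if (ext == "mzml") read_spectra_mzml(path, features, config)
  else stop("unsupported spectrum format: .", ext)
}

#' @rdname read_spectra
#' @export
read_spectra_msp <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^NAME:", lines[i], ignore.case = TRUE)) { i <- i + 1L; next }
    name <- trimws(sub("^NAME:", "", lines[i], ignore.case = TRUE))
    prec <- NA_real_; npk <- NA_integer_
    i <- i + 1L
    while (i <= length(lines) && !grepl("^Num Peaks:", lines[i], ignore.case = TRUE)) {
      if (grepl("^PRECURSORMZ:", lines[i], ignore.case = TRUE))
        prec <- as.numeric(trimws(sub("^PRECURSORMZ:", "", lines[i], ignore.case = TRUE)))
      i <- i + 1L
    }
    if (i > length(lines)) stop("MSP block for '", name, "' lacks Num Peaks")
    npk <- as.integer(trimws(sub("^Num Peaks:", "", lines[i], ignore.case = TRUE)))
    pk <- matrix(numeric(0), ncol = 2)
    i <- i + 1L
    while (i <= length(lines) && nzchar(trimws(lines[i]))) {
      xs <- as.numeric(strsplit(trimws(lines[i]), "[ \t]+")[[1]])
      pk <- rbind(pk, xs[1:2])
      i <- i + 1L
    }
    if (nrow(pk) != npk)
      stop("MSP block for '", name, "': expected ", npk, " peaks, found ", nrow(pk))
    out[[length(out) + 1L]] <- ms2_spectrum(name, prec, pk)
  }
  out
}

#' @rdname read_spectra
#' @export
read_spectra_mzml <- function(path, features = NULL, config = default_config()) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hd <- mzR::header(ms)
  ms2 <- which(hd$msLevel == 2)
  out <- list()
  for (k in ms2) {
    pk <- mzR::peaks(ms, k)
    gid <- NA_character_
    if (!is.null(features)) {
      dmz <- abs(features$mz - hd$precursorMZ[k])
      drt <- abs(features$rt - hd$retentionTime[k] / 60)
      cand <- which(dmz <= config$precursor_window_mz & drt <= 0.5)
      if (length(cand)) gid <- features$group_id[cand[which.min(dmz[cand])]]
    }
    out[[length(out) + 1L]] <- ms2_spectrum(gid, hd$precursorMZ[k], pk)
  }
  out
}

#' Write spectra as MSP text
#'
#' @param spectra List of `ms2_spectrum`.
#' @param path Output file.
#' @param comments Optional named character vector (per spectrum index) of
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_spectra_msp <- function(spectra, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    writeLines(c(paste0("NAME: ", sp$feature_group_id),
                 paste0("PRECURSORMZ: ", format(sp$precursor_mz, digits = 10))),
               con)
    if (!is.null(comments) && !is.na(comments[i]) && nzchar(comments[i]))
      writeLines(paste0("COMMENT: ", comments[i]), con)
    writeLines(paste0("Num Peaks: ", nrow(sp$peaks)), con)
    if (nrow(sp$peaks))
      writeLines(paste(format(sp$peaks[, 1], digits = 10),
                       format(sp$peaks[, 2], digits = 10)), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- reference standards and candidate tables ------------------------------

#' Read reference standards
#'
#' Standards carry identity (`analyte_id`, SMILES and/or formula), an
#' expected retention time and optional calibration points in a companion
#' CSV (`analyte_id`, `conc_ugL`, `response`).
#'
#' @param path Standards CSV.
#' @param calibration_path Optional calibration-points CSV.
#' @return Data frame of standards with a `calibration` attribute.
#' @export
read_standards <- function(path, calibration_path = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("analyte_id", "rt")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("standards table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"smiles" %in% names(d)) d$smiles <- NA_character_
  if (!"formula" %in% names(d)) d$formula <- NA_character_
  for (i in seq_len(nrow(d)))
    if (!is.na(d$smiles[i]) && nzchar(d$smiles[i]) &&
        (is.na(d$formula[i]) || !nzchar(d$formula[i])))
      d$formula[i] <- mf_render(mol_formula(mol_from_smiles(d$smiles[i])))
  cal <- NULL
  if (!is.null(calibration_path)) {
    cal <- read.csv(calibration_path, stringsAsFactors = FALSE)
    reqc <- c("analyte_id", "conc_ugL", "response")
    missc <- setdiff(reqc, names(cal))
    if (length(missc)) stop("calibration table missing column(s): ",
                            paste(missc, collapse = ", "))
  }
  attr(d, "calibration") <- cal
  d
}

#' Read a candidate-structure table
#'
#' Local stand-in for database retrieval: CSV with `candidate_id` and
#' `smiles` (compound candidates) or `formula` (formula candidates).
#'
#' @param path CSV file path.
#' @return Data frame of candidates.
#' @export
read_candidates <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"candidate_id" %in% names(d))
    stop("candidate table missing column: candidate_id")
  if (!"smiles" %in% names(d) && !"formula" %in% names(d))
    stop("candidate table needs a smiles or formula column")
  d
}
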