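# Packaged demo inputs: suspect lists emulating multi-source aggregation,
# reference standards with synthetic calibration series, and a local
# candidate-structure database (drug-like decoys shipped as plain CSV).

#' Demo suspect lists
#'
#' Structure suspects for the four demo parents with multi-source tags
#' (prediction algorithms `CTS`/`BTE`/`BTH`, literature `LIT`, database
#' `PC`), including suspects that are not planted in the simulation (so
#' screening has true negatives), plus metabolic-logic formula suspects
#' for every parent.
#'
#' Some planted TPs are deliberately absent from the lists (`hidden`), so
#' the unknown-screening workflow has work to do.
#'
#' @param seed Seed for the deterministic source-tag assignment.
#' @param hidden TP ids left out of the suspect lists.
#' @return Aggregated `suspect_list`.
#' @export
demo_suspects <- function(seed = 1L,
                          hidden = c("APH_SMX", "MPH_MET", "AMP_FLE",
                                     "ACA_PHE", "MPA_PHE", "FOA_PHE")) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tps <- demo_tps()
  tps <- tps[!tps$tp_id %in% hidden, , drop = FALSE]
  src_pool <- c("CTS", "BTE", "BTH", "LIT", "PC")
  rows <- lapply(seq_len(nrow(tps)), function(i) {
    ns <- sample(1:3, 1)
    data.frame(suspect_id = paste0("S_", tps$tp_id[i]),
               parent_id = tps$parent_id[i], kind = "structure",
               smiles = tps$smiles[i], formula = NA_character_,
               sources = paste(sort(sample(src_pool, ns)), collapse = ";"),
               label = tps$label[i], stringsAsFactors = FALSE)
  })
  # plausible but unplanted suspects (negatives for the screen)
  extra <- rbind(
    c("S_NP1", "SMX", "Nc1ccc(cc1)S(=O)(=O)Nc1ccccc1", "N-phenyl variant"),
    c("S_NP2", "MET", "CC(C)NCC(O)COc1ccc(C=O)cc1", "aldehyde variant"),
    c("S_NP3", "PHE", "O=C1CC(=O)N(c2ccccc2)N1C", "dioxo variant"),
    c("S_NP4", "FLE", "O=C(NCC1CCCCN1)c1ccccc1", "des(bis-ether) variant"))
  rows <- c(rows, lapply(seq_len(nrow(extra)), function(i)
    data.frame(suspect_id = extra[i, 1], parent_id = extra[i, 2],
               kind = "structure", smiles = extra[i, 3],
               formula = NA_character_,
               sources = paste(sort(sample(src_pool, 2)), collapse = ";"),
               label = extra[i, 4], stringsAsFactors = FALSE)))
  structure_sus <- suspect_list(do.call(rbind, rows))
  parents <- demo_parents()
  logic <- lapply(seq_len(nrow(parents)), function(i)
    logic_formula_suspects(structure_record(parents$parent_id[i],
                                            parents$smiles[i])))
  aggregate_suspects(c(list(structure_sus), logic))
}

#' Demo reference standards with calibration series
#'
#' Standards for the four parents (quantified on the M+2 isotope channel
#' to avoid detector saturation) and for two confirmed TPs (aniline and
#' 3-amino-5-methylisoxazole). Calibration series follow the serial
#' two-fold dilution design from 250 ug/L (parents) / 150 ug/L (TPs),
#' with responses generated from the demo response factors.
#'
#' @return List with `standards` (data frame) and `curves` (named list of
#'   `calibration_curve`).
#' @export
demo_standards <- function() {
  p <- demo_parents()
  tps <- demo_tps()
  std_tp <- tps[tps$tp_id %in% c("ANI_SMX", "AMI_SMX"), ]
  standards <- data.frame(
    analyte_id = c(p$parent_id, "ANI", "AMI"),
    smiles = c(p$smiles, std_tp$smiles),
    rt = c(p$rt, std_tp$rt),
    channel = c(rep("M+2", nrow(p)), "monoisotopic", "monoisotopic"),
    stringsAsFactors = FALSE)
  standards$formula <- vapply(standards$smiles, function(s)
    mf_render(mol_formula(mol_from_smiles(s))), character(1))
  rf <- c(setNames(p$response_factor, p$parent_id),
          ANI = 5e5, AMI = 5e5)
  curves <- list()
  for (i in seq_len(nrow(standards))) {
    a <- standards$analyte_id[i]
    f <- mf_parse(standards$formula[i], names(.tp_isotopes))
    top <- if (a %in% p$parent_id) 250 else 150
    conc <- top / 2^(0:4)
    mw <- mf_mass(f)
    chan_frac <- if (standards$channel[i] == "M+2")
      isotope_pattern(f, 2)$abundance[3] else 1
    resp <- rf[[a]] * (conc / mw) * chan_frac
    curves[[a]] <- fit_calibration(
      data.frame(conc_ugL = conc, response = resp), analyte_id = a,
      channel = if (standards$channel[i] == "M+2") "M+2" else "monoisotopic")
  }
  list(standards = standards, curves = curves)
}

#' Demo candidate-structure database
#'
#' Local stand-in for database retrieval: the packaged drug-like decoy
#' structures (including organohalogens and organophosphates that
#' exercise the element filter) plus, optionally, extra structures
#' appended by the caller (e.g. the planted TPs, emulating a database
#' that contains the true answer).
#'
#' @param extra Optional data frame (`candidate_id`, `smiles`) appended.
#' @return Candidate data frame (`candidate_id`, `name`, `smiles`).
#' @export
demo_candidate_db <- function(extra = NULL) {
  path <- system.file("extdata", "decoy_structures.csv", package = "tpscreen")
  db <- read_candidates(path)
  if (!is.null(extra)) {
    extra$name <- extra$candidate_id
    db <- rbind(db[c("candidate_id", "name", "smiles")],
                extra[c("candidate_id", "name", "smiles")])
  }
  db[!duplicated(db$candidate_id), ]
}
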