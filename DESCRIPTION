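Package: tpscreen
Title: Non-Target Screening and Elucidation of Transformation Products from
    Designed Degradation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to elucidate transformation products (TPs) of organic
    micropollutants from designed degradation experiments analysed by LC-HRMS
    non-target analysis. Implements feature prioritization by regression of
    peak intensity against initial parent concentration, multi-source suspect
    screening by accurate mass, parent-TP linking with single-parent-experiment
    pruning, MS2 formula and in-silico fragment annotation, ranking of unknown
    candidate structures by maximum common substructure fit, fingerprint
    similarity and annotation scores, automated identification-confidence
    assignment, calibration- and response-factor-based semi-quantitation with
    molar mass balances, and reporting. Includes a synthetic-experiment
    generator so the complete workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp,
    ChemmineR,
    ChemmineOB
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
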