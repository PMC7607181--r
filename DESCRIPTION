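Package: ihcmet
Title: Metabolic Phenotyping of Tumors from Immunohistochemistry and
    Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("TMA", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying glycolytic and gluconeogenic marker
    expression in tumor cohorts. Computes immunohistochemistry (IHC)
    combined scores (intensity x density, 0-300) on tissue-microarray
    cores, calls marker positivity, classifies tumors into
    glycolytic / gluconeogenic / mixed / unspecified metabolic phenotypes
    from GLUT1, PCK1 and PCK2 staining, and summarizes cohorts.
    Re-implements a deterministic margin-versus-center pipeline for
    H-DAB brightfield slides: optical-density color deconvolution,
    invasive-margin geometry via Euclidean distance transforms,
    macrophage and artefact exclusion, and stain-area quantification.
    Includes from-scratch survival and rank statistics (Kaplan-Meier
    with Greenwood intervals, logrank, Cox proportional hazards with
    Breslow or Efron ties, exact Mann-Whitney U, Spearman correlation),
    qPCR 2^ddCp quantification and densitometry normalization, and
    synthetic-data generators (TMA cohorts, H-DAB-like slides, qPCR
    plates) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
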