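Package: seprogadic
Title: Serum-Protein Prognostic Modules for Resected Gastric Cancer from
    Targeted MRM Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a serum-protein prognostic
    pipeline for resected gastric cancer: replicate-based quality control of
    multiple-reaction-monitoring (MRM) peak areas, endogenous-protein
    normalization with per-sample scaling factors and per-peptide ionization
    exponents, time-dependent ROC univariate screening, cross-validated Cox
    proportional-hazards stability selection with a binomial Z stopping rule,
    and construction of prognosis and adjuvant-therapy-selection modules.
    Includes a synthetic-cohort generator with known ground truth (batch
    drift, peptide-specific ionization response, pooled QC runs, triplicated
    samples, proportional-hazards outcomes) for recovery and calibration
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    boot,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
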