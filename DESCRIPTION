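Package: pdcscreen
Title: Pharmacogenomic Analysis of Patient-Derived Tumor Cell Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pharmacogenomic analysis of
    high-throughput drug screens run on patient-derived tumor cell (PDC)
    models, as used in gastric cancer precision-oncology cohorts. Converts
    raw plate luminescence into DMSO-normalized viabilities, fits
    four-parameter logistic dose-response curves and summarizes each
    (sample, drug) pair as the area under the fitted curve (AUC) with
    Z'-factor plate quality control; filters mutation calls, builds
    sample-by-alteration matrices with explicit unknown-status handling and
    assigns EBV/MSI/HCNA/LCNA molecular subtypes; runs Wilcoxon rank-sum
    gene-drug and subtype-drug association screens with Benjamini-Hochberg
    correction and Fisher co-occurrence tests; scores single-sample gene-set
    enrichment (ssGSEA); and extracts robust per-drug biomarkers by
    bootstrapped elastic-net stability selection. Ships a synthetic-cohort
    generator with planted ground-truth effects so every stage is testable
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
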