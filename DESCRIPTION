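Package: lfqmc
Title: Label-Free Shotgun-Proteomics Quantification with Monte Carlo
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for label-free quantitative shotgun proteomics:
    peptide-spectrum-match (PSM) filtering with target-decoy false discovery
    rate estimation, protein assembly under the two-peptide rule with
    array-based sequence coverage, redundancy reduction by spectra-set protein
    grouping, MS1 extracted-ion-chromatogram (XIC) elution-profile
    integration with noise-level imputation, mode-based intensity
    normalization, and Monte Carlo resampling tests for differential protein
    expression. Includes a fully seeded synthetic-data generator (protein
    databases with randomized decoys, tryptic digestion, Gaussian elution
    peaks over a noise floor, PSM tables) so every stage is testable without
    raw spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
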