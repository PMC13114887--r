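Package: cbmnscreen
Title: Radioprotector Screening with the Cytokinesis-Block Micronucleus Assay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing cytokinesis-block micronucleus (CBMN)
    scoring data in radioprotector screening studies. Fits linear (and
    linear-quadratic) micronucleus dose-response calibration curves with an
    exact inverse for biological dosimetry, estimates gamma-ray dose
    equivalents from observed micronucleus frequencies, and scores candidate
    substances by magnitude of protection (MP) and dose reduction factor
    (DRF), with DMSO solvent normalisation, genotoxicity assessment, one-way
    ANOVA with Tukey HSD pairwise comparisons, and a donor-by-treatment
    interaction screen. Includes a seeded synthetic CBMN data generator that
    emulates a multi-donor screening design so the full pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
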