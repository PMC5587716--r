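Package: histoneMRM
Title: Absolute Quantification of Circulating Histones by Targeted MRM
    Mass Spectrometry
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Targeted proteomics workflow for absolute quantification of
    circulating histones H2B and H3 in plasma by multiple reaction
    monitoring (MRM) with stable-isotope-labelled spike-in peptides.
    Provides in-silico tryptic digestion, proteotypic peptide selection
    and light/heavy transition-list design; conversion of per-transition
    light/heavy peak-area ratios into ng/mL plasma concentrations through
    spike-in standard curves, total plasma protein and protein molecular
    mass; a synthetic-data generator emulating calibration series and a
    septic-shock cohort; and biomarker evaluation (group summaries with
    95% confidence intervals, Student's t comparisons, Pearson
    correlation, and ROC analysis with Hanley-McNeil standard errors and
    Youden-index optimal cutoffs).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
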