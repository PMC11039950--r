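Package: mrbiome
Title: Two-Sample Mendelian Randomization for Summary-Level Microbiome
    Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) with GWAS summary
    statistics, built for taxon-abundance exposures and binary disease
    outcomes.  Covers instrument selection (p-value thresholding, greedy
    LD clumping, F-statistic filtering, confounder blacklists), allele
    harmonization with palindrome removal, five causal estimators
    (fixed- and random-effects inverse-variance weighting, MR-Egger,
    weighted median, weighted mode) and an MR-PRESSO-style resampling
    outlier test, heterogeneity and leave-one-out diagnostics,
    Benjamini-Hochberg significance classification across taxa,
    reverse-direction analysis, and a synthetic summary-statistics
    generator with known ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
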