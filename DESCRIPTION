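Package: perimr
Title: One-Sample Mendelian Randomization of Perinatal Exposures from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for one-sample Mendelian randomization (MR) from
    GWAS summary statistics, built around the perinatal-factor / amblyopia-risk
    setting: instrument selection (p-value filter, greedy LD clumping, exclusion
    lists, per-SNP F-statistics), allele harmonization with palindromic-SNP
    handling, four causal estimators (fixed- and multiplicative-random-effects
    inverse-variance weighting, simple and weighted median), MR-Egger regression
    with its intercept pleiotropy test, Cochran's Q heterogeneity diagnostics,
    and non-centrality-based statistical power for binary outcomes. A synthetic
    GWAS summary-statistics generator with known ground truth makes every stage
    testable without any data download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
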