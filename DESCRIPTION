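Package: ratioscore
Title: Two-Gene Expression Ratio Panels for Blood-Based Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates diagnostic classifiers from quantitative
    PCR gene-expression data.  Implements the ratioscore method: a resampled
    search over all ordered two-gene expression ratios for those that
    separate a case cohort from a control cohort, greedy assembly of a
    minimal ratio panel with control-maximum thresholds, and integer
    scoring of subjects by the number of panel ratios they exceed.  The
    same ratio features feed soft-margin kernel classifiers (radial-basis
    or polynomial) trained either by random-subset grid search or by
    cross-validated holdout, a three-class extension, and a tiered
    decision scheme for inflammatory bowel disease subtyping.  Includes a
    seeded synthetic cohort generator emulating a 47-probe TaqMan
    low-density array, Welch-test differential expression with Bonferroni
    correction, and confusion/ROC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
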