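Package: npirep
Title: Nonparametric Predictive Inference Bootstrap Reproducibility for
    Two-Sample Tests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the reproducibility probability of one-sided
    two-sample hypothesis tests (the pooled-variance t-test and the
    Wilcoxon-Mann-Whitney test) by nonparametric predictive inference
    (NPI) bootstrap resampling, and the reproducibility of a final
    dose-selection decision built from sequential pairwise comparisons
    with Benjamini-Hochberg adjustment.  Ships the dose-response
    case-study data, a simulation module relating reproducibility to the
    p-value and Cohen's d, frequency-table and tree summaries of decision
    outcomes, and seed-reproducible JSON/CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
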