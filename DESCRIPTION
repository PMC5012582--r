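Package: trendmr
Title: Dose-Response Trend Conversion, Meta-Analysis, and Two-Sample
    Mendelian Randomization for Anthropometric Cancer Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the association between adult height and
    cancer risk from published summary data. Converts per-quantile categorical
    relative risks into continuous per-10-cm log relative-risk trends using the
    Greenland-Longnecker pseudo-count method with Il'yasova-style scores for
    open-ended categories; pools study estimates by inverse-variance-weighted
    fixed-effect and REML random-effects meta-analysis with Cochran's Q,
    tau-squared, I-squared, and subgroup homogeneity tests; assesses funnel-plot
    asymmetry with Begg's rank correlation and Egger's regression; and performs
    two-sample summary-statistic Mendelian randomization (allele harmonization,
    the inverse-variance-weighted estimator, MR-Egger pleiotropy regression,
    pleiotropy-exclusion sensitivity analysis, and instrument power via the
    Burgess non-centrality approximation). Includes synthetic-data generators
    that emulate GWAS summary statistics, study collections with between-study
    heterogeneity and small-study selection, and cohort quantile tables, so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
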