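Package: pathsurv
Title: Pathway-Based Survival Analysis for Multi-Study Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Survival-oriented gene-set analysis for transcriptomic cancer
    cohorts. Provides per-gene Cox proportional-hazards scans under several
    model specifications with Benjamini-Hochberg false discovery rate
    control, covariate-adjusted gene-set analysis built on the maxmean
    statistic with restandardization and permutation p-values, generalized
    Sidak-Holm (k-FWER) pathway selection, pathway risk index (PRI) scoring
    with median-split survival stratification inside clinical cohorts,
    cross-study comparison tables, and a synthetic multi-study generator
    with proportional-hazards survival for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
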