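Package: cessnet
Title: Penalized Candidate-Gene Association Analysis of Long-Term Smoking
    Cessation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for case-control candidate-gene studies of
    smoking cessation: univariate behavioral association statistics (odds
    ratios with Woolf confidence intervals, chi-square and Fisher exact
    tests, two-group comparisons), a single-nucleotide variant filtering
    cascade (variation, missingness, duplicate-profile collapse,
    complete-case subsetting, additive 0/1/2 coding), elastic-net penalized
    logistic regression fit by coordinate descent on an iteratively
    reweighted quadratic approximation, leave-one-out cross-validated AUC
    model selection over an (alpha, lambda) grid, and post-selection
    (selective) inference for the LASSO-selected model via the polyhedral
    lemma with truncated-Gaussian p-values. Includes a synthetic
    genotype-phenotype cohort simulator with Hardy-Weinberg genotypes,
    block linkage disequilibrium, planted effects, and structured
    missingness, so the whole pipeline is testable without access to
    individual-level study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
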