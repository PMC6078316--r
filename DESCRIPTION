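Package: oobias
Title: Out-of-Bag Error Bias in Subsampling Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the upward bias of the out-of-bag (OOB) error
    of random forest classifiers built on without-replacement subsamples.
    Provides a subsampling forest with explicit in-bag bookkeeping and three
    per-tree sampling schemes (unstratified, stratified with class-proportional
    fractions, and balanced equal-per-class sampling), five error estimators
    (independent test error, OOB, stratified OOB, 10-fold cross-validation and
    stratified 10-fold cross-validation) with class-specific variants,
    synthetic null- and power-case data generators with unbalanced class
    ratios, correlated genomic-like feature matrices and permutation-null
    transforms, exact hypergeometric theory for the class composition of
    subsamples, class-preference diagnostics, and seeded Monte-Carlo study
    drivers for quantifying the bias and its consequences for tuning the
    mtry parameter.
License: MIT
Encoding: UTF-8
Imports:
    ranger,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
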