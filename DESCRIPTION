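Package: wpcor
Title: Valid Inference for the Weighted Pearson Correlation Coefficient
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Point estimation and hypothesis testing for the Pearson
    correlation coefficient computed with per-observation probability
    weights. Provides the delta-method large-sample variance of the
    weighted estimator, an asymptotic test, studentized permutation tests
    (including Fisher-Z variants), a de-correlation construction for
    testing non-zero null correlations, weight-generation schemes
    (order-statistic spacings and regression leverage), and a Monte Carlo
    harness for type-I error and power studies across six bivariate
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
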