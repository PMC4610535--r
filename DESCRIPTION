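Package: kfsurvey
Title: Constrained Kalman-Filter Estimation for Sample Surveys with Census Auxiliary Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Model-assisted survey estimation in which a design-based
    multivariate estimate (vector mean and covariance from a simple random
    sample) is updated by a sequential scalar Kalman filter so that the
    estimated population means of auxiliary variables -- typically remotely
    sensed layers enumerated for every population unit -- exactly equal their
    known census values. The constraint reduces the variance of every study
    variable correlated with an auxiliary variable. Includes the design-based
    initial estimator, a post-stratification comparator with stratum
    collapsing and design-effect reporting, covariance sparsification by
    correlation testing, delta-method pseudo-estimators for post-estimation
    transforms (sums, differences, products, ratios), a finite-population
    simulator with annual-panel sampling, and a Monte-Carlo efficiency
    harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, MASS, jsonlite
Suggests: testthat (>= 3.0.0), yaml, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
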