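Package: lcsmm
Title: Latent Change Score Mixture Models for Longitudinal Symptom Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits latent change score models (LCSM) and their finite-mixture
    extension (LCSMM) to wide-format longitudinal symptom panels such as
    repeated PHQ-9 assessments, using full-information maximum likelihood so
    that records with partially missing waves are retained. Provides
    multi-start EM estimation with within-class latent variance fixed to
    zero, class-enumeration reports (information criteria, relative entropy,
    minimum class size, log-likelihood replication), bias-adjusted 3-step
    regression of class membership on covariates and of distal binary
    outcomes on class (Vermunt / Bolck-Croon-Hagenaars corrections), and a
    synthetic-cohort generator that emulates a nine-wave pandemic-period
    depression panel for testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), nnet, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
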