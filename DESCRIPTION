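Package: catgrm
Title: Graded Response Model Calibration and Computerized Adaptive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for developing computerized adaptive tests (CAT) for
    ordinal rating-scale instruments under Samejima's graded response model
    (GRM). Provides the full item-bank development pipeline used for
    patient-reported mood measures: descriptive item screening
    (unused categories, item-remainder correlations), checks of the IRT
    assumptions (principal-component unidimensionality, residual-correlation
    local dependence, Mokken scalability), marginal maximum likelihood (EM)
    calibration of the GRM, maximum a posteriori trait scoring, S-X2 item
    fit, likelihood-ratio differential item functioning screens, a
    Fisher-information-driven adaptive testing engine with standard-error
    stopping, CAT simulation with trait-recovery metrics, and concurrent /
    discriminant validity statistics. A synthetic-data generator reproduces
    the statistical structure of a Likert-type mood survey so every stage of
    the pipeline can be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
LinkingTo: Rcpp
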