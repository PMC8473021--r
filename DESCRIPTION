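Package: dentage
Title: Dental Age Estimation from Pantomogram Landmark Ratios with
    Radial Basis Function Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates chronological age (in months) of children and
    adolescents from manual landmark measurements on panoramic dental
    radiographs (pantomograms).  Computes a set of 21 dimensionless
    tooth and bone ratio indicators from named 2-D landmarks, fits
    radial basis function (RBF) regression networks under a reproducible
    2:1:1 train/validation/test protocol with an automatic candidate
    search, and performs sensitivity-quotient analysis with input-layer
    pruning and retraining.  Includes a synthetic cohort generator with
    monotone growth trajectories so the full pipeline is testable
    without clinical data, and a command-line front end.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
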