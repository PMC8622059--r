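Package: landsec
Title: Land Ecological Security Evaluation with AHP and Fuzzy Comprehensive
    Evaluation
Version: 0.1.0
Authors@R:
    person("landsec", "developers", email = "landsec@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate land ecological security from multi-year
    indicator panels. Implements linear dimensionless normalization of
    positively and negatively oriented indicators, analytic hierarchy
    process (AHP) weighting from pairwise judgment matrices with
    consistency control (lambda_max, CI, RI, CR), fuzzy comprehensive
    evaluation (FCE) with triangular membership functions against an
    ordered assessment set, weighted-average synthesis of per-year group
    and comprehensive security scores, land-use structural change
    analysis, and a synthetic-data generator with known ground truth for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
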