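Package: prsmediate
Title: Polygenic Risk Scoring and Mediation of Educational Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline linking polygenic risk scores for
    attention-deficit hyperactivity disorder (ADHD) to educational and
    cognitive outcomes across two generations. Implements discovery-weight
    polygenic scoring (P-value thresholding, LD pruning, log odds-ratio
    weighting), covariate-adjusted association with Nagelkerke pseudo-R2
    differences and likelihood-ratio tests, Sobel-Goodman and bootstrap
    mediation, and two-mediator decomposition via seemingly unrelated
    regression. A synthetic-data module simulates a liability-threshold
    case-control discovery sample, Mendelian mother-child duos, and
    phenotypes with a configurable mediation structure, so every stage is
    exercisable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
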