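Package: sumscores
Title: Sum Scores, Reliability, and Factor-Score Regression for Classical Test Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A measurement toolkit for classical test theory. Computes weighted
    and unit-weight composite (sum) scores with their exact moments, fits
    constrained single- and multi-factor confirmatory factor models by maximum
    likelihood (congeneric, essentially tau-equivalent, essentially parallel,
    with optional mean structure), and estimates reliability by coefficient
    alpha, coefficient omega-total, factor-score and sum-score reliabilities
    with their correlation, and the composite reliability of a sum of
    components with known reliabilities. Includes four predictor-to-outcome
    strategies for scored scales (sum-score regression, Croon-corrected factor
    score regression, and simultaneous latent-variable regression), a
    synthetic-data generator for factor-model item pools with criterion
    variables, and a split-sample cross-validated validity harness.
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
    withr,
    yaml
Config/testthat/edition: 3
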