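Package: nbemeta
Title: Meta-Analysis of Net Biodiversity Effects on Invasion Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multilevel meta-analysis of log-response-ratio effect
    sizes quantifying how plant diversity affects invasion resistance under
    environmental change. Computes net biodiversity effects (NBE), their
    change under manipulated conditions (delta-NBE), and environmental factor
    effects, with delta-method sampling variances and the shared-control
    variance-covariance structure; fits three-level random-effects
    meta-regression by restricted maximum likelihood with known sampling
    covariance; provides Q_M moderator tests, Bonferroni-corrected marginal
    means, pairwise Wald contrasts, Egger funnel-asymmetry tests, Cook's
    distance influence diagnostics, and a synthetic-data generator with known
    ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
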