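Package: growthqr
Title: Regularized Quantile Regression for Genomic Growth Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step genomic analysis of animal growth trajectories.
    Step one fits a three-parameter logistic growth model to each
    animal's weight-age records and corrects the parameter estimates
    (mature weight, inflection age, growth scale) for fixed effects.
    Step two estimates SNP marker effects on those corrected traits by
    L1-penalized (regularized) quantile regression, solved exactly as a
    linear program by a primal-dual interior-point method, with penalty
    selection over a grid by predictive capacity, Koenker-Machado
    pseudo-R1 goodness of fit, and bootstrap standard errors for the
    top-ranked markers. Genomic estimated breeding values (GEBVs) and
    quantile-specific genomic growth curves with bootstrap confidence
    bands are derived from the fitted marker effects. A simulator for
    F2-cross genotypes (Haldane map function) and logistic phenotypes
    with age-increasing residual variance makes the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
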