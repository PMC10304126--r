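Package: metstab
Title: Stability and Performance Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing balanced multi-environment yield trials
    (METs) laid out as randomized complete block designs: joint fixed-effects
    ANOVA, AMMI (additive main effects and multiplicative interaction) model
    families with Gollob F-tests and a signal/noise partition of the
    genotype-by-environment sum of squares, ANOVA-based variance components
    and BLUP shrinkage of genotype means, the WAASB stability index with
    yield-by-stability quadrant classification, GGE biplot mathematics with
    ideal-genotype ranking, replicate-holdout cross-validation comparing the
    AMMI family against BLUP by root-mean-square prediction difference, and a
    weather-covariate module (period aggregation, Pearson screening, partial
    least squares regression).  A synthetic-data generator with fully known
    additive and multiplicative structure makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    mixOmics
Config/testthat/edition: 3
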