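Package: metstab
Title: Stability Analysis for Multi-Environment Yield Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genotype-by-environment stability analysis for multi-environment
    yield trials laid out as randomized complete block designs. Provides the
    combined analysis of variance and AMMI (additive main effects and
    multiplicative interaction) decomposition of the genotype-by-environment
    interaction with Gollob F-tests, seven AMMI-based stability indices (ASV,
    SIPC, EV, Za, MASV, D, WAAS) with simultaneous selection indices,
    mixed-model (BLUP) genotypic values with the HMGV, RPGV and HMRPGV
    stability-adaptability statistics, factorial regression of the interaction
    on environmental covariates with AIC forward selection, NIPALS partial
    least squares regression of the interaction on covariates, and a synthetic
    trial generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
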