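Package: crossedpower
Title: Simulation-Based Power Analysis for Mixed-Effects Models with
    Crossed Random Intercepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo power analysis for linear and generalized
    (binomial-logit) mixed-effects models with crossed random intercepts,
    as used in designs where participants respond to samples of stimuli.
    Simulates new response vectors from a fully specified model, resizes
    designs along participant or item grouping factors, refits each
    simulated dataset and estimates power as the proportion of significant
    refits, with exact (Clopper-Pearson) binomial confidence intervals.
    Supports smallest-effect-size-of-interest (SESOI) coefficient
    overrides, two-random-variable scans, type-I-error simulation by
    zeroing effects, and construction of fully crossed artificial designs
    and models from scratch when no pilot data exist.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
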