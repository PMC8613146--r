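---
title: "Simulation-based power for crossed mixed models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power for crossed mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crossedpower)
```

## The problem

Mixed-effects models with crossed random intercepts — participants and
stimuli both sampled, every participant seeing every stimulus — have no
usable closed-form power solution beyond very simple one-effect
designs. `crossedpower` estimates power empirically: if the generative
model is fully specified, the planned experiment can be simulated, and
power is the proportion of simulated experiments in which the effect of
interest comes out significant.

## The model

For a Gaussian response,

$$ y = X\beta + \sum_g Z_g b_g + \varepsilon, \qquad
   b_g \sim N(0, \sigma_g^2 I), \quad \varepsilon \sim N(0, \sigma_e^2 I), $$

where $X$ is the fixed-effect design (intercept, main effects,
elementwise-product interaction columns) and $Z_g$ the indicator matrix
of grouping factor $g$ (subjects, items). For a binary response the
linear predictor is passed through the logistic link and the response
is Bernoulli. The random structure is intercepts only — no random
slopes or correlations; designs needing them are out of scope.

Estimation is delegated to lme4: REML for Gaussian models, Laplace
maximum likelihood (conditional modes via penalized iteratively
reweighted least squares) for binomial ones. Significance is judged on
the Wald statistic $\hat\beta_i / \mathrm{SE}_i$ against a critical
value, with strict inequality $|stat| > crit$. We deliberately avoid
p-values: denominator degrees of freedom in crossed designs are
ambiguous, while $|t| > 2$ (Gaussian) and $|z| > 1.96$ (binomial)
correspond to a nominal $\alpha \approx 5\%$ and are the package
defaults. Per-effect criteria are supported for mixed
confirmatory/exploratory designs.

## The simulation loop

For each target level count $s$ of the scanned grouping factor
(`simvar`) and each repetition $r = 1 \dots nsim$:

1. the design is **resized** along `simvar` to $s$ levels. Shrinking
   keeps a uniform random subset of existing levels with all their
   rows. Growing clones whole level blocks — covariates intact, fresh
   IDs appended after the existing levels — cycling through the source
   levels in shuffled order. Cloning preserves the observed covariate
   joint distribution exactly; we do not invent a covariate model for
   new participants. Covariates are *not* recentered after resizing
   (recentering is the caller's explicit choice). In a two-factor scan
   (`run_r2_scan`) a second factor is then resized to its fixed level.
   Responses are resized along for the ride but are never used: the
   response is re-simulated next.
2. a **new response vector** is simulated from the generative model.
   Random-intercept values are drawn per level (one per subject, one
   per item) and redrawn on every repetition — each repetition is a new
   sample of participants and stimuli.
3. the model is **refit** to the simulated data and each effect's Wald
   statistic is thresholded.

Power per effect, step and mode is $100 \cdot k / n_{valid}$ with an
exact Clopper–Pearson binomial interval (beta-quantile construction;
closed at 0 and 100). We default to 95% intervals and report
$k$, $n_{valid}$ and $n_{failed}$ alongside.

### Modes: databased and SESOI

The *databased* mode simulates from the model's own coefficients —
appropriate when they come from well-powered pilot data. Because
published effect sizes may be inflated, the *sesoi* mode accepts a full
replacement coefficient vector (smallest effect size of interest; a
simple convention is all coefficients shrunk by 15% with the intercept
kept) and runs the same repetitions with it. Both modes share
per-repetition seeds, so their comparison is paired: on the same
simulated "worlds", shrunken effects can only lose power up to Monte
Carlo noise.

### Type-I simulation

`estimate_type1` zeroes every non-intercept coefficient and reruns the
scan; the rejection rate then estimates the realized type-I error of
the chosen thresholds under the design's random-effect structure. With
the default thresholds it should sit near 5% (the Wald-t criterion of 2
is slightly conservative in large designs and slightly liberal in very
small ones, where the reference distribution has few effective degrees
of freedom).

### Failed refits

Refits can fail outright (constant simulated response, complete
separation, hard non-convergence). Failed refits enter neither the
numerator nor the denominator; they are tallied per cell as
`n_failed`, and a warning fires when failures exceed 5% of `nsim`.
Convergence *warnings* (including boundary/singular fits, which are
expected when a variance component is small) are kept as valid refits,
flagged `converged_with_warning` — discarding them would bias power at
exactly the small-variance designs power analysis cares about.

## Determinism and seeds

Every repetition derives its seeds — one for resizing, one for
simulation — from (base seed, step index, repetition index) through a
31-bit multiplicative rolling hash. Consequences: a scan is exactly
reproducible from the plan's single seed; results are independent of
execution order; and databased/sesoi modes are seed-paired. Refitting
is deterministic (fixed optimizer and starting values), so the whole
power table is a pure function of (model, data, plan, rule).

Two numerical choices worth noting:

- GLMM refits default to `glmerControl(calc.derivs = FALSE, optimizer
  = "nloptwrap")`. Skipping the post-hoc derivative check and using
  nloptr's BOBYQA is about 3× faster per refit than lme4's default
  two-stage optimizer; on our fixtures the Wald z values agree with
  the default optimizer to well below any significance-relevant margin
  (a regression test asserts agreement to 0.02).
- Variance components live on lme4's bounded scale (standard-deviation
  parameterization, lower bound 0), so boundary estimates are exact
  zeros with a singular-fit flag, not negative values.

## From-scratch designs

When no pilot data exist, `make_crossed_design` builds the full cross
of the grouping factors (first factor fastest; every level pair exactly
once), `assign_categorical` adds a block-constant coded predictor whose
allocation over blocks follows a ratio by largest-remainder rounding
(deterministic in level order by default, so a balanced two-group
design is literally first half / second half), and `sample_continuous`
attaches one normal draw per level of a factor (e.g. one frequency per
word), optionally grand-mean centered *after* replication — in
unbalanced designs this centers on observations, not levels. Centering
is idempotent. `make_artificial_model` then wraps user-chosen
coefficients and variances into a generative model with no fitting.
Variance components should be passed as a named vector; unnamed
positional vectors are accepted with a warning, because silent
positional swaps between subject and item variances are an easy and
consequential mistake.

Continuous predictors are drawn once per generated design and held
fixed across a scan's repetitions, mirroring the workflow of creating
the artificial dataset once and then simulating responses; the
predictor's realized distribution therefore contributes between-design
(not between-repetition) variability to the power estimate. The
reference conditions used throughout examples and tests
(`make_lexdec_design` / `make_lexdec_model`) emulate a lexical-decision
accuracy study: 20 subjects × 100 words, NativeLanguage ∈ {−0.5, +0.5}
balanced over subjects, Frequency ~ Normal(5, 1) centered, binomial
model with β = (−4.3, 0.35, −0.4, −0.32) and variances 1.04 (Subject) /
0.65 (Word) — plausible magnitudes for accuracy data with strong
subject heterogeneity, at which the NativeLanguage effect is
deliberately underpowered at 20 subjects (≈ 15–17%).

### What the generator does and does not emulate

The artificial designs are fully crossed and balanced, covariates are
exactly block-constant, frequency ratings are exactly normal, and the
generative model is exactly the fitted model's family. Real datasets
have missingness, partial crossings, non-normal covariates and model
misspecification, all of which move power. Passing tests on these
designs therefore validates the machinery — simulation, resizing,
counting, intervals — not the transferability of any particular power
number to a messier real design; the accuracy of a real power estimate
is bounded by the accuracy of the generative model supplied.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `nsim` | 1000 | repetitions per step; Monte Carlo SE of a power estimate near 50% is ≈ 1.6 points at 1000 and ≈ 5 points at 100. 1000 is the recommended minimum for a final analysis; exploratory scans can run smaller. |
| `critical` | 2 (Gaussian), 1.96 (binomial) | Wald threshold per effect; raising it lowers estimated power. |
| `level` | 0.95 | confidence level of the power intervals. |
| `steps` | — | target level counts of `simvar` (each ≥ 2). |
| `sesoi` | off | full coefficient vector, intercept included. |

Scan cost is essentially `nsim × steps × modes` refits; a 2000-row
binomial refit takes ~0.3 s on one core, a few-hundred-row Gaussian
refit ~0.04 s. The shipped test suite runs its scans at nsim 150–200
(with the correspondingly widened acceptance bands) and the acceptance
script at the full nsim = 1000.

## Degenerate inputs and edge cases

Zero variances simulate exact means; an all-zero/all-one binomial
response is a failed refit, not an exception; constant covariates with
an intercept are rejected as rank-deficient before any fitting; resize
targets below 2 levels are range errors; grouping-level IDs are
compared as strings, with first-appearance level order and fresh IDs
appended on growth.

## Known limitations

Intercept-only random structure; Gaussian and binomial-logit families
only; no p-value-based significance, multiplicity correction, or
joint/conditional power across effects (power is per effect — sample
size decisions should follow the weakest effect of interest); growing
a factor reuses observed covariate blocks rather than modelling the
covariate distribution; Wald-threshold calibration is approximate in
very small designs.
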