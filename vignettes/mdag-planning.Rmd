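---
title: "Planning multivariable missing-data analyses with m-DAGs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning multivariable missing-data analyses with m-DAGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdagplan)
```

# The model and its assumptions

## m-DAGs

An m-DAG is a DAG over three kinds of nodes: substantive variables, latent
variables, and binary missingness indicators. Indicator `M_V` equals 1
exactly when variable `V` is unobserved; the *observed* version of `V` is
then a deterministic function of `(V, M_V)` and is never drawn as a
separate node. Three structural assumptions are enforced or surfaced by
`validate_mdag()`:

* **(i)** no latent variable is a common cause of a variable and its own
  missingness indicator (violation code `ASSUMPTION_I`);
* **(ii)** all common causes of analysis variables and indicators are on
  the graph — this cannot be machine-checked, so validation always emits a
  user-attestation warning (`ASSUMPTION_II`);
* **(iii)** missingness indicators have no outgoing arrows: missingness is
  a terminal event, it does not cause anything substantive
  (`ASSUMPTION_III`).

Groups of variables that are always measured together (e.g. items of one
questionnaire) may be collapsed to a single node carrying
`group_members`; the collapsed node is treated atomically throughout.

## Recoverability and the canonical catalogue

Whether an estimand is recoverable is determined by the *key arrows*: the
arrows from the exposure `X`, outcome `Y`, and incomplete confounder block
`Z` into the indicators `M_X`, `M_Y`, `M_Z`. `classify_canonical()` maps
the observed key-arrow set to a canonical label:

* the full 9-arrow grid ({X, Y, Z} each into all three indicators) is the
  canonical mechanism labelled **J** — the regression coefficient is *not
  recoverable*;
* the 6-arrow set with only `X` and `Z` as parents of the indicators is
  labelled **E** — *recoverable*;
* any other set gets a signature label `other:<signature>` plus a
  `nested_in` attribute pointing at the smallest canonical superset.

`lookup_recoverability()` applies the *nesting rule*: a mechanism whose
arrows form a subset of a canonical mechanism inherits that mechanism's
verdict only when the verdict is "recoverable" (removing arrows cannot
break recoverability, but it can restore it, so non-recoverable verdicts
never propagate downward). Everything else is reported as
`undetermined` — the package is deliberately conservative and never
guesses. The catalogue is a data frame, so users can extend it with
`canonical_catalogue(overrides = ...)` as new results become available.

## The complete-records criterion

Independently of recoverability, a complete-records regression is
consistent when selection into the complete records is uninformative
about the outcome given the regressors:

```r
d_separated(g, "Y", all_indicators, c(exposure, covariates))
```

`d_separated()` is a Bayes-ball reachability implementation, tested
against an exhaustive path-enumeration oracle over all labelled DAGs on
up to four nodes and a thousand random 5–6-node DAGs.

## The planner

`plan_analysis()` combines the verdicts: recoverable, CRA-valid, and no
auxiliaries → CRA; recoverable otherwise → MI; not recoverable →
delta-adjusted MI over the *elicited* delta grid (an error if no grid is
supplied — deltas encode external knowledge the package cannot invent);
undetermined → the plan says so explicitly. Alternative plausible m-DAGs
are carried as sensitivity analyses in the user's order.

# The synthetic case study

`case_study_model()` emulates a cohort analysis of a binary exposure on a
continuous outcome:

* `C` and `Z` are standard-normal confounder blocks with `C → Z`
  coefficient 0.3 (`Z` collapses three jointly measured variables);
* `X ~ Bernoulli(plogis(−1.6 + 0.4 C + 0.4 Z))`, giving a realistic
  exposure prevalence around 20%;
* `Y ~ Normal(16 + 0.6 X + 1.5 C + 1.5 Z, 5²)`, clipped to `[0, 40]` to
  mimic a bounded score.

The target parameter is the conditional coefficient of `X`, true value
0.6. Clipping affects well under 1% of draws; the full-data coefficient at
n = 2,000,000 is 0.5987, so the clipped generator's estimand is treated as
0.6 within Monte Carlo error (tests compare against 3 Monte Carlo standard
errors, never against clipping-free algebra).

## Missingness mechanisms and calibration

Each indicator follows a logistic model with slope 0.5 on its parents
(`X` and `Z` in variant "a"). Intercepts are *calibrated*, not set by
hand: `calibrate_intercepts()` solves
`mean(plogis(a + lp)) = target` by `uniroot` over `[−40, 40]` on an
n = 200,000 reference sample, for targets 0.15 (`M_X`), 0.23 (`M_Y`),
0.19 (`M_Z`). Calibrating the *marginal* proportion rather than the
intercept keeps the realized missingness at the target regardless of the
covariate distribution.

Variant "b" adds `Y` to every indicator's parent set with a log-odds
coefficient of 1 *per outcome standard deviation* (i.e. raw coefficient
`1 / sd(Y)`), so the strength of outcome-driven missingness is expressed
on an interpretable scale and does not silently change if the outcome
variance changes.

Variant "pm" is a pattern-mixture probe used to validate delta
adjustment: only `Y` is missing, `M_Y` depends on `X` (coefficient 0.7),
clipping is off, and the *unobserved* outcomes are shifted by a known
`pattern_delta`. The implied true coefficient is computed analytically as
`0.6 + pattern_delta * (plogis(a + 0.7) − plogis(a))`, which is what the
Monte Carlo tests compare against.

**Realism and limits.** The generator is linear-Gaussian/logistic by
construction: it reproduces the qualitative structure (confounding,
multivariable missingness, outcome-dependent selection) but not
non-linearities, interactions, or heteroscedasticity. Its purpose is to
make the graphical verdicts empirically checkable, not to imitate any
particular dataset.

# Estimation machinery

## FCS imputation with exact delta offsets

`fcs_impute()` is a fully conditional specification engine: initialize
missing cells from observed marginals, then cycle over incomplete
variables, drawing each from a proper Bayesian linear model (scaled
inverse-χ² draw for the variance, Cholesky-based normal draw for the
coefficients) or, for binaries, a large-sample normal draw around the
logistic MLE. A delta offset is added to imputed cells of a continuous
variable *after* each draw.

Two exactness contracts are enforced and tested:

* **delta = 0 is a bitwise no-op**: the offset addition is skipped
  entirely when the delta is zero, so a zero-delta run is `identical()`
  to a no-delta run;
* **equal RNG consumption across deltas**: runs at different deltas from
  the same seed consume the random stream identically, so with a single
  incomplete outcome the mean imputed value moves *exactly* one-for-one
  with the delta. With several incomplete variables the shift feeds back
  through subsequent cycles, so exact one-for-one movement is only
  guaranteed — and only tested — in the single-incomplete-variable case.

Deltas on binary variables are rejected: an additive offset has no
coherent meaning on the 0/1 scale.

## Pooling

`pool_rubin()` implements Rubin's rules with total variance
`W + (1 + 1/m) B` and Barnard–Rubin small-sample degrees of freedom (with
the large-sample formula as the `df_com = Inf` limit).

# Evaluation tools

`monte_carlo()` reports bias, empirical SE, the Monte Carlo SE of the
bias (`empirical_se / sqrt(R)`), and 95% interval coverage; failing
replicates are excluded, counted, and warned about (all-fail is an
error), so a fragile estimator cannot silently look unbiased.

`empirical_recoverability_probe()` runs CRA and MI arms at escalating
sample sizes and asks whether the absolute bias *shrinks* with n (a
consistent estimator's bias falls like 1/√n; a non-recoverable one's does
not). The result is a coarse signal — `recoverable-by-CRA`,
`not-recoverable-signal`, or `inconclusive` — and deliberately never
overrides the graphical verdict: simulation can contradict a graph (which
is worth knowing) but cannot certify it.

# Numerical and design choices

* **Simulation sizes** in the shipped tests (e.g. 200 replicates at
  n = 5,000–10,000; m = 20 imputations, 10 cycles for the coverage check)
  are package choices balancing Monte Carlo error against runtime; all
  comparisons use 3 Monte Carlo SEs or the conventional coverage band
  [0.92, 0.975] for 200 replicates.
* **Determinism**: serialization sorts nodes and edges, every stochastic
  routine takes an explicit seed, and re-running a workflow from the same
  config is byte-identical.
* **The case-study default n = 4,882** matches a typical cohort size for
  analyses of this kind and yields complete-record fractions near 56%
  under the calibrated mechanisms.
* **Config-driven execution** (`run_workflow()`, the CLI in
  `inst/cli/mdagplan.R`) keeps the plan, the data provenance, and the
  results in one reproducible artifact.
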