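---
title: "Methods: bidirectional MR screening with sensitivity batteries and Bayesian model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional MR screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The problem

Two-sample Mendelian randomization (MR) uses genetic variants as
instrumental variables to test whether genetic liability to an exposure
causally affects an outcome, using only GWAS summary statistics from two
(ideally non-overlapping) samples. A screen over many candidate traits —
for instance, testing a psychiatric index trait against dozens of
anthropometric, cognitive, lifestyle and mental-health traits in both
directions — multiplies every weakness of a single MR analysis: weak
instruments, horizontal pleiotropy, reverse causation, and multiple
testing. `mrscreen` packages the full staged defence a careful screen
uses, exercised end to end on synthetic summary statistics so every stage
is testable without any external download.

## Stages and estimators

**Trait screening.** Candidate GWAS are filtered on study metadata:
sample size (effective size `4 n_case n_control / (n_case + n_control)`
for case-control studies) above 5000, more than 450&nbsp;000 variants,
European ancestry, non-sex-specific, more than three independent
genome-wide significant signals, and — to focus on traits where causal
signal is plausible — heritability Z above 4 and genetic-correlation Z
(with the index trait) above 2. These Z scores are consumed as metadata;
computing them is out of scope.

**Harmonization and instrument selection.** Exposure and outcome tables
are aligned to a common effect allele, with strand-complement handling
and frequency-based orientation of palindromic variants (dropped above a
minor-allele frequency of 0.42, where frequency no longer identifies the
strand — this policy is a package default, exposed as a knob, since
public pipelines differ). Instruments are genome-wide significant
(`p < 5e-8`) variants greedily clumped at `r2 < 0.001` within 10 Mb;
variants significant in both traits are removed; instruments missing
from the outcome may be replaced by LD proxies at `r2 >= 0.8`. Proxy
outcome effects are taken as tagging the original variant's effect
allele; with an unsigned `r2` table, proxy sign alignment relies on the
LD reference being phase-consistent, a documented simplification.

**The estimator battery** (`mr_fit()`) comprises:

* *Multiplicative random-effects IVW* (main analysis): weighted
  regression through the origin with weights `1/se_out^2`; Cochran's Q
  on `L - 1` df yields `I2 = max(0, (Q - df)/Q)`; the standard error is
  scaled by `max(1, sqrt(Q/df))`. The floor (never shrinking below the
  fixed-effect SE) matches the dominant implementation convention; a
  pure multiplicative variant is a switch. P-values use the normal
  reference by convention; `t` is available.
* *MR-Egger*, after orienting all instruments to positive exposure
  effects, with the intercept as the pleiotropy test. The `I2GX`
  statistic (precision-weighted dispersion of the exposure effects)
  measures regression dilution under the no-measurement-error
  assumption: above 0.9 Egger is used as-is, in (0.6, 0.9] the SIMEX
  correction is applied, at or below 0.6 the Egger result is
  disregarded. The precision-weighted form of `I2GX` was chosen (the
  unweighted alternative sits behind a configuration switch) because the
  weights match those used in the Egger fit itself.
* *SIMEX*: for each noise multiplier in `{0.5, 1, 1.5, 2}`, B = 1000
  replicates add `N(0, lambda se_exp^2)` noise to the oriented exposure
  effects, the Egger slope is refit and averaged, a quadratic in lambda
  is extrapolated to `lambda = -1`, and the Monte-Carlo error is
  jackknifed over simulation batches and added to the naive slope's
  sampling variance. Orientation is fixed before noise is added.
* *Weighted median and weighted mode*: ratio-based estimators robust to
  invalid instruments; the mode uses a normal-kernel weighted density
  with a modified-Silverman bandwidth (factor 1.0 by default). Standard
  errors use a parametric bootstrap (B = 1000, explicit seed) because
  the original method descriptions do so; `boot_B = 0` gives
  estimate-only fits for large simulation studies.
* *MR-PRESSO* (`mr_presso()`): the global test simulates the null
  distribution of the leave-one-out residual sum of squares; per-variant
  outlier tests are Bonferroni-adjusted over the L instruments, flagged
  outliers removed, and IVW refit. Simulation p-values use the add-one
  estimator so they are never exactly zero. Per-variant RNG streams are
  keyed by variant id, making results invariant to instrument order.
  The distortion comparison is reported as a note, not a formal test.
* *Steiger filtering*: instruments must explain more variance in the
  exposure than the outcome (strict inequality; an optional
  directionality z-test is off by default since "substantially more" has
  no canonical quantitative definition). Variance explained is
  `t^2/(t^2 + n - 2)` for continuous traits and the liability-scale
  conversion from the log odds ratio for binary traits (logistic
  observed-scale R2 with residual variance `pi^2/3`, then the
  case-control-to-liability correction with the ascertainment factors
  `C` and `theta`; genotype variance is taken as `2p(1-p)`). Prevalence
  defaults to the sample case proportion, with a message, because that
  default biases the conversion when ascertainment is strong.
* *F statistics*: per-SNP `(b/se)^2`, their mean, and the aggregate
  `((n - L - 1)/L) R2/(1 - R2)`. Both are emitted since conventions
  differ on which is "the" F statistic; the sensitivity rule uses the
  mean, with 10 as the usual strength rule of thumb, for continuous
  exposures.

**Evidence rules** (`evaluate_sensitivity()`, `classify_pair()`). A
direction passes the main stage when the Benjamini–Hochberg FDR-adjusted
IVW p is below 0.05 (pooled over all tests run in the screen — the most
literal reading of "FDR across all tests"; per-direction pooling is a
switch). It passes the sensitivity stage when the weighted median,
weighted mode, MR-PRESSO and Steiger-filtered IVW all agree with the IVW
direction at p below 0.05, the Egger/SIMEX track agrees whenever the
intercept signals pleiotropy, and the mean F exceeds 10 for continuous
exposures. When Egger must be disregarded (`I2GX <= 0.6`) while
pleiotropy evidence exists, the strict default fails the pair — the
conservative resolution of a corner the evidence rules leave open; a
lenient policy skips the check instead. Directions passing sensitivity
proceed to the Bayesian model comparison, with a Bonferroni threshold
over the number of comparisons actually run (not a hard-coded count).

## The sharing-versus-causal model comparison

`cause_lite()` adjudicates correlated pleiotropy — variants acting on
both traits through a shared heritable factor — which the regression
battery cannot see. Each variant's pair of observed effects
`(b_X, b_Y)` is modelled with true exposure effect `beta` drawn from an
empirical zero-mean normal-mixture prior (fit by an EM deconvolution
with a point-mass null component; the observed-data log-likelihood is
non-decreasing by construction). With probability `q` the variant acts
through the shared factor and the outcome mean is
`(gamma + eta) beta`; otherwise it is `gamma beta`. The *sharing* model
pins the causal effect `gamma` at 0; the *causal* model leaves it free.
Priors are `gamma, eta ~ N(0, 0.6^2)` and `q ~ Beta(1, 10)`, following
the spirit of the published method; all are configurable.

Posteriors are computed by adaptive grid integration (41 points for
`gamma`, 31 for `eta`, 25 midpoint nodes for `q`): a coarse pass spans
three prior standard deviations, expands once automatically if more than
1% of mass reaches the boundary (then errors), and a refinement pass
re-grids the region holding the central mass. Grid posteriors make the
whole fit deterministic — no MCMC, no seed sensitivity — and fast enough
for hundreds of fits in a simulation study. The cost is grid-resolution
granularity in extreme tails (visible only when the data carry almost no
information, where summaries are prior-dominated to within a grid step).

Models are scored by the difference in expected log pointwise posterior
density. The package uses in-sample log pointwise predictive densities
under each grid posterior, with the standard error `sqrt(L) sd` of the
per-variant differences — a deliberate simplification of the reference
method's Pareto-smoothed importance-sampling leave-one-out estimate. All
calibration properties (null centring, false-positive avoidance, power)
are therefore tested behaviourally rather than by equality to the
reference implementation. The reported `delta_elpd` is
`elpd(sharing) - elpd(causal)`: negative values favour the causal
model, `z = delta/se`, and the one-sided p is `pnorm(z)`. Identical
fits give `delta = 0` and `p = 0.5` by definition.

Why this comparison has power despite the sharing model being able to
mimic any causal fit with `q -> 1, eta = gamma`: the `Beta(1, 10)` prior
on `q` makes that mimicry expensive, so under a true causal effect the
sharing posterior compromises and fits each variant slightly worse; the
summed per-variant deficit grows with L while its standard error grows
as `sqrt(L)`. Under pure correlated pleiotropy both models fit equally
well and the comparison stays at chance — the property that protects a
screen from this failure mode, at the price of conservatively shrunk
causal estimates (the prior on `gamma` is centred at zero).

## The synthetic-data generator

`simulate_pair()` generates the exact structure the analysis assumes:
true exposure effects from a configurable normal mixture (default a
single `N(0, 0.05^2)` component — strong enough that most variants pass
genome-wide significance at the default n of 100 000, mimicking a
well-powered GWAS of a heritable trait); outcome effects
`gamma beta + eta Z beta + theta` with `Z ~ Bernoulli(q)` shared-factor
indicators and sparse uncorrelated pleiotropy `theta`; optional
reverse-causation variants whose primary effect is on the outcome
(`N(0, 0.1^2)`, back-propagated with coefficient 0.5 — large enough to
reach exposure significance, so they genuinely contaminate the
instrument set until Steiger filtering removes them); standard errors
from the standardized-genotype asymptotics
`1/sqrt(2 maf (1 - maf) n)`, inflated by `1/sqrt(phi(1 - phi))` for
case fraction `phi` on the log-OR scale; minor-allele frequencies
uniform on (0.1, 0.5); independent estimation error in the two samples
(an overlap correlation knob exists, default 0). Binary margins can also
be produced through a liability-threshold route that exactly inverts the
liability-scale conversion, making round-trip tests sharp.

Optional LD blocks emit groups of consecutive variants tagging a shared
lead signal at a configured `r2`, together with the matching pairwise LD
reference — enough structure to exercise clumping and proxy lookup.
What the generator deliberately does *not* emulate: realistic LD decay
from a reference panel, allele-frequency-dependent architectures,
population stratification, or dynastic/assortative-mating effects.
Passing tests therefore demonstrate correctness of the estimators and
decision logic under the two-sample summary-statistic model, not
robustness to every failure mode of real GWAS data.

All randomness flows from one seed through per-variant counter streams
keyed by variant id (with a nonlinear scramble so streams for related
keys are independent); output is byte-identical across runs and row
orders.

## Numerical choices and degenerate inputs

* P-values are floored at the smallest positive double; generated
  p-values likewise, so extremely strong instruments survive validation.
* IVW with fewer than 2 instruments, Egger/median/mode with fewer than
  3, and PRESSO with fewer than 4 return explicit not-applicable
  results rather than errors; empty clumping output and empty
  harmonization intersections propagate as empty results the pipeline
  records as verdicts.
* Clumping ties in p are broken lexicographically by variant id;
  without an LD reference, distance-only clumping applies with a
  warning.
* The Egger intercept's interpretation requires the positive-exposure
  orientation; it is applied inside the fit, and SIMEX adds noise after
  orienting, without re-orientation.
* The EM prior fit pins component 1 at sd 0 for K of at least 2 and
  stops on a relative log-likelihood change of 1e-6; non-convergence
  returns the best iterate with a warning flag.

## Simulation study sizes

The packaged acceptance checks use the following desk-scale but
statistically meaningful conditions, chosen once as the package's study
conditions: null calibration with L = 50 instruments, n = 100 000, 2000
replicates (IVW) and 200 replicates of the PRESSO global test with 1000
null simulations each; parameter recovery at gamma = 0.3 with L = 100,
n = 200 000, 500 replicates; correlated-pleiotropy false-positive
avoidance at eta = 0.3, q = 0.3 with L = 100, 100 replicates; SIMEX
attenuation runs with L = 100 instruments and outcome standard errors an
order of magnitude below the exposure ones, so the dilution bias —
the thing SIMEX corrects — dominates sampling noise in the win-rate
comparison; and a fixed-seed reverse-causation fixture with 30% reverse
variants. The standalone-pair FDR correction applies BH over the two
directions; in a full screen the pool is every IVW test run.

## Known limitations

* The model-comparison ELPD uses in-sample predictive densities, not
  cross-validated ones; its p-values are calibrated in our simulations
  but are not numerically interchangeable with the reference tool's.
* Proxy substitution assumes sign-consistent LD tagging (no phase
  information is consumed).
* Liability-scale conversion uses genotype variance `2p(1-p)`; tools
  that use `p(1-p)` will report values differing by a factor of 2 in
  observed-scale variance before the nonlinear correction.
* Ordered-categorical traits are analysed exactly as continuous; the
  label affects only reporting, mirroring how such traits are commonly
  exported.
* The trait screen consumes heritability and genetic-correlation Z
  scores as given; no LD-score regression is performed.
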