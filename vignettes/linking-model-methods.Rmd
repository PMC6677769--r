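---
title: "Linking cortical population responses to perceptual choice: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking cortical population responses to perceptual choice: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexreadout)
library(dplyr)
```

## The scientific problem

Human observers can report about either the contrast or the motion
coherence of a pair of random-dot patches while ignoring the other
feature. Both features drive overlapping responses across retinotopic
visual cortex, so a downstream decision stage must somehow separate
them. Two implementations are possible: the sensory representations
themselves could change with the task (attention reshaping the code), or
the representations could stay stable while a *readout* — the weighting
of cortical areas feeding the decision — changes flexibly with the task.
`flexreadout` implements the full modeling pipeline needed to arbitrate
between these accounts: a generative simulator of the two-feature 2AFC
task and its BOLD correlates, psychometric and population-response
fitting, probit linking models with fixed or task-flexible readouts, and
cross-validated model comparison.

## The linking model

Each visual area's mean response to a dot patch is parameterized as a sum
of a Naka–Rushton contrast term, a saturating-exponential coherence term,
and an additive offset:

$$R_{area}(s_{con}, s_{coh}) = \alpha_{con}\,
\frac{s_{con}^{1.9}}{s_{con}^{1.6} + \sigma^{1.6}}
+ \alpha_{coh}\left(1 - e^{-s_{coh}/\kappa}\right) + \alpha_{task}.$$

A note on the coherence exponent: written with a positive exponent the
expression would grow without bound and run negative for positive
amplitudes; the function is a *saturating* nonlinearity whose scale
constant $\kappa$ marks the point where it reaches $1 - e^{-1} \approx
63\%$ of its asymptote, which forces the negative sign used here.
Because $\alpha_{coh}$ and $\kappa$ are not interpretable in isolation,
coherence sensitivity is summarized by the least-squares linear slope of
the coherence curve on a 101-point grid over $[0, 1]$
(`coherence_linear_slope()`); tests check this grid slope against the
closed-form projection of the exponential onto the $\{1, s\}$ basis.

The decision stage weights the per-area responses evoked by the two
patches into scalars $\Sigma_{right}, \Sigma_{left}$, and the probability
of reporting "right" is a probit with lapse:

$$P_{right} = \frac{\lambda}{2} + (1 - \lambda)\,
\Phi\!\left(\Sigma_{right} - \Sigma_{left} + \beta_{bias}\right).$$

A **fixed** readout shares one weight per area across the two tasks
(9 parameters for eight areas); a **flexible** readout fits one weight
per area per task (17 parameters for eight areas, 5 for the two-area
V1/MT model). Three variants probe the modeling assumptions:

* **Stay/switch history** — four extra coefficients driven by the
  previous trial's side and accuracy, entering the decision variable
  additively. The first trial of each run carries no history.
* **Efficient selection** — area responses are raised (sign-preservingly)
  to an exponent $\rho \ge 1$ before weighting and the $\rho$-th root of
  the aggregate is taken, so high-amplitude areas dominate. The
  sign-preserving power keeps negative responses and biases defined for
  non-integer $\rho$.
* **Poisson-like noise** — the probit scale is not 1 but the square root
  of the mean *unweighted* population response of the two patches,
  $\sigma^2 = \tfrac{1}{2}(\bar R_{right} + \bar R_{left})$, placing the
  response-dependent variability in the sensory stage, before readout.
  Averaging the two patch variances (rather than summing them) was a
  genuinely open choice; we average, which keeps $\sigma$ on the scale of
  a single patch's response and reduces to the additive model when
  responses are constant.

Because the probit noise is fixed at 1, the fitted weights carry an
interpretation: a unit difference in weighted response yields threshold
performance, so the implied sensory noise of area $a$ is
$\sigma_a = 1/|\beta_a|$ percent signal change (`implied_noise()`).

### Predicted thresholds and the two JND conventions

The analytic just-noticeable difference at a base stimulus is the
increment that raises the weighted readout by a criterion number of noise
standard deviations, found by bisection to $10^{-7}$ stimulus units
(`predict_jnd()`; a grid-search oracle at $10^{-5}$ resolution backs it
in the tests). Two criteria coexist in the signal-detection literature
and are not mutually consistent: a *unit readout difference* ($d' = 1$ on
the decision variable) implies $\Phi(1) \approx 84\%$ choice accuracy,
while the conventional "~76% correct" threshold corresponds to
$\Phi(1/\sqrt{2})$, i.e. a readout difference of $1/\sqrt{2}$. We default
to the unit-difference convention for model JNDs and expose `target =
1/sqrt(2)` for the 76% convention; descriptive Weibull thresholds always
use the 76% criterion ($d' = 1$ with independent per-patch noise).

Catch-trial predictions come in two modes (`predict_catch_jnd()`): the
*wrong-readout* prediction evaluates the probed feature under the other
task's weights — when those weights are insensitive to the feature the
JND is non-measurable, i.e. the model predicts the task cannot be done —
and the *memory-cost* prediction keeps the correct readout but inflates
the required response difference by a scalar cost factor, equivalent to
scaling the noise. The generative observer applies this cost on post-cued
trials; its default of 2.83 is the scale of working-memory costs the
behavioral literature reports for this task family.

## The synthetic task and observer

`task_config()` defaults encode the study conditions: base increments of
+7.5/+15/+30/+60% contrast above a continuously visible 25% baseline and
+15/+30/+45/+60% coherence above 0%; fixed menus of un-cued target
increments; 2/5 of behavioral runs are catch runs using a single base
increment (+30% contrast, +40% coherence) in which each trial is
post-cued with probability 1/7; inter-trial intervals are exponential
with mean 6 s truncated to 2–11 s (the rate is solved numerically so the
*truncated* mean is 6 s, and draws use the inverse CDF). Base conditions
are drawn i.i.d. uniformly on the 4 × 4 grid, which makes every condition
equally likely to follow every other — the property the chi-square
balance check (`check_condition_balance()`) verifies. Contrast and
coherence are proportions in $[0, 1]$ internally; percentages appear only
at I/O boundaries.

The cued feature's increment is controlled by a PEST adaptive staircase
(`run_pest_staircase()`), one independent staircase per task × base
strength (8 in the standard design), targeting 82% correct. The original
PEST papers leave freedom in the details; we implement the classic rules:
a Wald sequential test with deviation bound 1 decides when the level is
reliably above or below target; steps halve on reversals and double after
repeated same-direction steps (with the classic exception following a
reversal that was preceded by a doubling); a step floor prevents
degeneracy; levels are capped at the displayable range ($base + level
\le 1$), and a staircase pinned at the cap is flagged as diverged.
Staircase initialization (25% contrast, 85% coherence) follows the task
description; the initial step size is not specified anywhere, so it is
exposed in `staircase_settings()` with a default of half the initial
level. Step sizes reset to a third of the current level every third run
to track slow drift. In simulation this procedure holds a Weibull
observer ($\tau = 0.10$, $\beta = 3$) at roughly 80–81% correct after
burn-in — the classic Wald criterion converges slightly below its nominal
target — which the acceptance script recomputes from scratch.

Choices are Bernoulli draws from the linking model's choice probability,
with correctness scored against the target side of the judged feature
(the post-cued feature on catch trials, which also incur the
working-memory cost and do not update the staircase, since no feedback is
given).

## BOLD simulation and deconvolution

Scan-mode schedules emit 0-based onset volumes at TR = 0.5 s.
`simulate_bold_timeseries()` sums, per event, an amplitude times a
canonical kernel shifted to the onset — the linear-summation assumption
the analysis inverts — plus i.i.d. Gaussian noise. The canonical kernel
(`canonical_hrf()`) is a difference of two gamma densities (peak near
5 s, undershoot near 15 s) normalized to unit peak; its exact shape was
an open choice and only its unit-amplitude contract matters, since
amplitudes are defined as least-squares scalings of it. Stimuli are
lateralized, so each hemisphere's series is driven by the contralateral
patch (`hemifield_amplitudes()`); the pipeline averages hemisphere
amplitude tables per area.

`build_fir_design()` constructs the Toeplitz-block stimulus convolution
matrix ($n \times k \cdot c$; 81 lags × 32 conditions = 2592 columns for
the full grid), stored sparse, with responses truncated at the series end
and half-open response windows $[onset, onset + k)$. `deconvolve()` is
ordinary least squares via the normal equations with a Cholesky solve,
falling back to a minimum-norm SVD solution (with a warning and a
diagnostic flag) when the design is rank deficient. The multicollinearity
diagnostic mirrors the standard check on randomized designs: the fraction
of off-diagonal Gram entries exceeding 10% of the corresponding diagonal.
Staircase-valued stimulus strengths are binned to the nearest base
strength before condition assignment, with ties rounding down toward the
base.

With the shape constants $\sigma$ and $\kappa$ held at passive-viewing
values, the per-task gain/offset model for the amplitude grid is *linear*
in $(\alpha_{con}, \alpha_{coh}, \alpha_{task})$, so
`fit_response_functions()` solves it exactly by least squares rather than
iteratively — six free parameters per area (three per task), recovered
exactly on noiseless tables.

## Fitting, cross-validation, and comparison

The lapse rate is estimated first, as twice the error rate on
suprathreshold trials (cued increments of at least +15% contrast or +40%
coherence, about twice threshold): under the lapse model asymptotic
accuracy is $1 - \lambda/2$, so the raw error rate is $\lambda/2$; the
raw rate is reported alongside. The lapse is then held fixed while
`fit_readout()` maximizes the Bernoulli likelihood over weights and bias
with bounded quasi-Newton iterations (weights in $[-50, 50]$, bias in
$[-10, 10]$, $\rho \in [1, 5]$) and seeded random restarts (a zero start
plus uniform draws). Per-trial area responses are precomputed once, so an
objective evaluation is two matrix–vector products; the Poisson-mode
scale does not depend on the parameters and is also precomputed.

`crossval_loglik()` implements 10-fold cross-validation with folds
stratified by task and base-strength cell (the fold scheme itself was
unspecified; stratification guarantees every fold contains both tasks),
deterministic under a fixed seed. Model comparison uses the difference in
total held-out log-likelihood in natural log units — greater than ~10
nats is treated as substantial — plus the cross-validated Tjur
coefficient of discrimination $CD = \mu_{right} - \mu_{left}$, the mean
held-out predicted probability of a rightward choice on right-choice
trials minus left-choice trials.

## What the generator does and does not emulate

The synthetic observer reproduces the statistical structure the analysis
assumes: probit choices from weighted population responses, lapses,
staircase-controlled difficulty, catch-trial post-cueing with a memory
cost, balanced randomized condition sequences, and linear hemodynamic
summation with white Gaussian noise (an AR(1) option exists in concept
but the default is white, as the measurement noise model is otherwise
unconstrained). It does not emulate: sensory adaptation or learning
across sessions, temporally correlated physiological noise, eye-movement
artifacts, voxel-level heterogeneity (responses are area-mean series), or
any change of the response functions *within* a run. Passing tests
therefore certify the estimators against their own generative
assumptions — parameter recovery, oracle equivalence, structural counts —
not robustness to real-data violations of those assumptions.

## Numerical choices and problem sizes

Default ground truth for the demonstration pipeline is the two-area
(V1, MT) flexible observer with weights $(\beta_{V1}, \beta_{MT}) =
(12, -2)$ for the contrast task and $(-1, 18)$ for the coherence task,
bias 0.1 and lapse 3%. These were chosen once so that predicted JNDs sit
at the empirically observed scale (~5% contrast at the lowest base, ~15%
coherence) and the contrast readout is nearly insensitive to coherence
(the negative MT weight cancels V1's small coherence response, the same
suppression pattern the fitted models exhibit). Passive-viewing response
parameters use the published per-area contrast amplitudes and coherence
slopes, with $\sigma = 0.5$ and a shared near-linear $\kappa = 3$ (the
amplitude is then solved so the linear slope matches the published
value).

Tolerances: bisection for JNDs to $10^{-7}$; optimizer convergence to
$10^{-8}$ on the objective; noiseless round-trip assertions at $10^{-8}$;
JSON serialization at 17 significant digits for lossless round-trips.
Test problem sizes (schedules of a few thousand trials, 10 recovery
seeds, $10^6$-draw Monte-Carlo oracles, two-condition-grid scan
simulations) were chosen as the smallest sizes at which the tested
properties are statistically decisive.

## Worked example

```{r example, eval = FALSE}
cfg <- validate_config(list(seed = 5, output_dir = tempfile(),
                            task = list(trials_per_run = 40, n_runs = 20),
                            comparison = list(n_folds = 5),
                            fitting = list(n_restarts = 2)))
report <- run_pipeline(cfg)
report$comparison$summary
#> # A tibble: 2 x 4
#>   model    total_cv_loglik    cd n_folds
#>   <chr>              <dbl> <dbl>   <dbl>
#> 1 flexible           -368. 0.409       5
#> 2 fixed              -465. 0.210       5
```

The flexible readout recovers most of the explainable structure (CD ≈
0.41 here, against ~0.44 reported for human observers at full scale) and
beats the fixed readout by ~97 nats of held-out log-likelihood on 800
trials — the qualitative signature that sensory changes alone cannot
explain task switching.

## Known limitations

* The history variant conditions on the immediately preceding trial
  within a run only; longer-range serial dependence is not modeled.
* The Poisson variant requires positive mean population responses; a
  floor of $10^{-8}$ guards degenerate all-zero parameterizations.
* Rank-deficient FIR designs (short scans relative to $k \cdot c$) yield
  minimum-norm solutions that are not interpretable per condition; the
  result carries a flag and downstream fits should not be trusted when it
  is set.
* `fit_cum_normal()` under complete separation drives $\sigma$ to its
  bound and flags the fit rather than failing.
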