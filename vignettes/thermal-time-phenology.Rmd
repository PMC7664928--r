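---
title: "Thermal-time modelling of olive phenophases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-time modelling of olive phenophases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermophen)
```

## The model

Olive development is tracked on the BBCH scale, a coding of discrete
phenophases (bud development, flowering, fruit set, ripening). The codes
themselves are labels, not numbers, so `thermophen` maps an ordered code
list to a dense integer rank 1..K and treats the rank as the target of a
regression problem whose errors are meaningful: predicting one stage off
is better than predicting five.

Development is driven by thermal time. Daily growing degree days above a
base temperature $T_b$ are computed two ways from daily minima and maxima:

* **simple average**: $\max\{0,\ (T_{\min}+T_{\max})/2 - T_b\}$;
* **single sine**: the day's temperature course is one sine wave with mean
  $m=(T_{\min}+T_{\max})/2$ and amplitude $a=(T_{\max}-T_{\min})/2$, and the
  day contributes the period-average of degree-hours above $T_b$, with no
  upper cutoff. In closed form, with $\theta=\arcsin((T_b-m)/a)$ when
  $T_{\min}<T_b<T_{\max}$,
  $$\mathrm{dd} = \frac{1}{\pi}\Big[(m-T_b)\big(\tfrac{\pi}{2}-\theta\big)+a\cos\theta\Big],$$
  reducing to $m-T_b$ when $T_b\le T_{\min}$ and to $0$ when
  $T_b\ge T_{\max}$.

Because the period-average of a full sine wave is invariant to phase, the
placement of the daily maximum within the 24 h does not change the result;
the closed form is validated in the test suite against numeric integration
of the hourly sine to below $10^{-6}$ °C·day. The single-sine value always
dominates the simple average (Jensen's inequality, since $\max(0,\cdot)$ is
convex), with equality when the base temperature does not cut the sine.

Cumulative GDD accumulates from January 1 of each year — a fixed convention
of the model, not a tunable. Negative simple-average days are clamped to
zero: a base temperature is by definition the level below which tissue is
not active, so negative accumulation has no biological meaning and would
break the monotonicity of the cumulative series.

## The models

**Threshold baseline.** The benchmark assigns each phase rank $k$ a
threshold $\theta_k$, the *mean* cumulative GDD of training observations in
that phase, and predicts the rank whose interval
$[\theta_k, \theta_{k+1})$ contains the query GDD. Values below the first
threshold give the smallest fitted rank; values at or above the last give
the largest; a value equal to the next phase's threshold belongs to the
next phase. Noisy data can produce non-monotone fitted thresholds; the
implementation replaces the sequence by its running maximum (with a
warning), which preserves the interval semantics. Ranks absent from
training are never predicted.

A structural property worth knowing: because $\theta_k$ is a *mean*, it
sits in the middle of phase $k$'s observed GDD band, so roughly the lower
half of each band is predicted one rank low even on noiseless data. The
baseline's combined metric therefore carries a floor of quantisation error
that no base temperature removes — which is why its
metric-versus-base-temperature curve is nearly flat and tends to drift to a
grid boundary, and why base-temperature recovery (below) uses a
boundary-learning model instead.

**Learner registry.** The remaining model families — linear regression,
CART, random forests, feed-forward neural networks, stochastic gradient
boosting, and linear/tree extreme gradient boosting — are called from their
standard R implementations behind a uniform `fit(X, y)` / `predict`
contract. Each family exists in a *linear-features* and a
*polynomial-features* variant (all monomials of total degree up to 4; two
base features give 14 columns). Continuous outputs are discretised (round
by default; floor and ceiling available) and clamped to $[1, K]$.
Hyperparameter grids default to a single sensible row (no tuning needed);
grids with several rows are resolved by an inner repeated k-fold
cross-validation (3×10 by default) on the training split only, minimising
RMSE of the continuous predictions. The registry is pluggable:
`register_model()` adds a family, and a family whose backing package is
missing fails with an explicit capability error rather than silently.
Stochastic learners are fitted under a local seed so a fitted pipeline is
reproducible end to end.

## Evaluation

Models are compared with repeated stratified splitting: 100 random 70/30
train/test partitions, stratified jointly by year and location so every
site and season appears on both sides of every split. Within a stratum of
$n_s$ rows the train share is `round(0.7 n_s)` (half rounded up);
singleton strata go wholly to training, where they can do no harm. Three
metrics are recorded per split:

* **accuracy** — exact-match fraction;
* **RMSE** — on the integer ranks (the ordering of stages makes distances
  meaningful; no ordinal weighting is applied);
* **combined** — $(1-\text{Accuracy})\times\text{RMSE}$, zero when either
  factor is perfect, otherwise the typical error size weighted by the
  error rate. Model selection minimises its resampled mean.

Each metric's mean over the repeats gets a Student-t confidence interval
(95% by default; the level is configurable). All candidates in a
comparison — and all base temperatures in a grid search — see the *same*
sequence of partitions (one shared `split_spec` seed), so split noise
cancels out of every comparison. Ties in model selection resolve to the
earliest candidate, and ties between grid temperatures to the lowest
temperature, both with a message.

## Base-temperature optimisation

`optimize_base_temp()` searches candidate base temperatures (default 0 to
10 °C in 0.5 °C steps, the customary range for olive; configurable for
other crops). Every candidate triggers a full recomputation: cumulative
GDD at that base, feature rebuild, and resampled refit — tuning included,
so nothing fitted at one temperature leaks to another. The per-metric
optimum is the grid member with maximum mean accuracy or minimum mean
RMSE / combined metric.

## The synthetic world

Real multi-year phenology campaigns are rarely redistributable, so the
package ships a generator whose ground truth is known exactly:

* **Station weather.** Per location, daily mean temperature is an annual
  sine (annual mean drawn from U(12, 18) °C, amplitude U(7, 11) °C, peak
  near late July) plus an AR(1) anomaly (coefficient 0.6, marginal sd
  2 °C); `tmin`/`tmax` sit half the diurnal range (U(8, 12) °C) below and
  above. The spread of annual means is what a coastal-to-hill Tuscan
  station network spans, and it matters: the base-temperature signal in
  any analysis comes from *cross-location misalignment* of GDD bands,
  which vanishes if all sites share one climate.
* **Reanalysis-like weather.** The station series shifted by a
  per-location constant offset (U(−1.5, 1.5) °C by default). A constant
  temperature bias biases every day's degree-days in the same direction,
  so the cumulative-GDD relative error against the station reference
  converges to a per-location constant — the signature that gridded
  reanalysis shows against ground stations, and the diagnostic
  `gdd_source_comparison()` tabulates.
* **Phenology.** A latent threshold process: the true rank at a visit is
  the largest $k$ whose threshold $\theta^*_k$ does not exceed cumulative
  single-sine GDD at the true base temperature. Default thresholds are
  derived from the noise-free mid-range climatology so all K = 20 stages
  occur within the visit season. Twelve visits per location-year between
  early March and late October, jittered by ±3 days; with 22 locations ×
  3 years this yields ~790 observations, matching the shape of a regional
  olive campaign (a few dozen sites, a few hundred points per year).
  Observed ranks are misrecorded by one stage with probability
  `p_noise = 0.15` — one-stage misreading being the plausible field error;
  larger residuals must come from model failure, not injected noise.

What the generator does *not* emulate: spatial correlation between
locations, heat waves and cold spells beyond AR(1) persistence, cultivar
differences, multi-day sensor dropouts, or reanalysis bias that varies
seasonally. Passing tests therefore demonstrate the correctness and
internal consistency of the pipeline, not field accuracy on any real
orchard network.

## Validation studies the package runs on itself

The test suite builds every expected value it asserts, either by hand
arithmetic, by an independent brute-force oracle (numeric sine
integration; explicit interval search for the baseline), or by
construction of worlds with known truth. Three studies deserve comment:

* **Noiseless closure.** With `p_noise = 0` and per-rank GDD bands that
  are point masses (identical climatologies, visits pinned to threshold
  crossings), the fitted baseline reproduces every observation exactly.
  This is the strongest statement the mean-threshold model admits: with
  any within-band spread its mid-band thresholds misclassify the lower
  half of each band, as explained above.
* **Parameter recovery.** Twenty replicate worlds with true base
  temperatures 2, 4, 6, 8 °C (five each, ~790 observations, 15% rank
  noise) are pushed through the full grid search with a CART scenario on
  the single-sine GDD feature (`cp = 2e-4`, `minsplit = 5` — deep enough
  to learn band boundaries). Resampling is reduced to 20 repeats per
  temperature to keep the study at ~2.5 minutes on one CPU. The
  combined-metric optimum is required to fall within one grid step
  (0.5 °C) of the truth in at least 90% of worlds; in the shipped
  configuration it does so in 20 of 20.
* **Learner versus baseline.** On the default world, whose targets have
  learnable DOY × GDD structure plus threshold noise, a default random
  forest's mean combined metric must not exceed the baseline's under
  paired splits; in practice it is about a factor three smaller.

## Numerical and degenerate-input choices

* `arcsin` arguments are clamped to $[-1, 1]$ against floating-point
  overshoot at branch boundaries; the branches agree to $10^{-9}$ there.
* A constant-temperature day ($a = 0$) falls into the closed form's
  boundary branches and returns $\max(0, m - T_b)$.
* Rank discretisation uses base R `round` (half-to-even); the discretiser
  is idempotent on valid integer ranks, which is the property models rely
  on.
* Zero-variance feature columns are tolerated everywhere: the linear
  model drops aliased coefficients, the neural net guards its input
  scaling, and tree learners ignore constant columns.
* Weather tables must be gap-free from January 1 within each
  location-source-year; a gap is an error naming the first missing day,
  never a silent interpolation.
* DOY follows the calendar: January 1 is day 1 and leap-year December 31
  is day 366. A constant offset in DOY cannot affect tree models and only
  shifts linear intercepts.

## Known limitations

The baseline never interpolates ranks missing from training. The rank map
shipped by `default_rank_map()` is a synthetic 20-stage stand-in, not an
official BBCH monograph subset — real studies must supply their own
ordered code list. Chilling accumulation, double-sine and triangle
degree-day variants, upper temperature cutoffs, and joint optimisation of
the accumulation start date are out of scope.
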