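---
title: "Measuring object-location binding in visual short-term memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring object-location binding in visual short-term memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vstmbind)
```

## The task and why its geometry matters

In the 'What was where?' delayed-reproduction task a participant studies 1
or 3 fractal objects placed pseudorandomly on a touch screen (about 62 ×
35° of visual angle at the study's viewing distance), retains them across
a 1 s or 4 s blank delay, then chooses between the studied *target* and a
*foil* drawn from the same stimulus pool, and drags the chosen object to
its remembered location. A session is a 10-trial practice block followed
by two 50-trial test blocks, each with 10 one-item and 40 three-item
trials and the two delays balanced within load (5/5 and 20/20).

Three placement constraints carry the entire analysis:

* items sit at least **3.9°** from every screen edge and **6.5°** from the
  screen centre, keeping reports away from hard boundaries;
* items within a trial are separated by more than **9°**;
* a report within **4.5°** of a non-target's original position counts as a
  *swap error*.

Because 2 × 4.5° does not exceed the 9° separation, the swap discs around
items are disjoint: a report can never be attributed to two different
items, which is what makes the swap classification well defined.
`screen_geometry()` enforces these invariants at construction, and
`validate_session()` re-checks every generated design and reports
violations as data rather than errors.

Several aspects of the session are under-determined by the task
description and were fixed here as design choices: coordinates are
continuous degrees of visual angle with the origin at screen centre (the
published pixel matrix maps linearly via `deg_to_px()`); margins apply to
item *centres*, since every metric is computed between centres; the probed
item is chosen uniformly per trial; and the practice block mirrors the
test-block composition at one-fifth scale (2 one-item + 8 three-item
trials, delays balanced) and is excluded from all summaries. Item
placement uses rejection sampling with a generous attempt budget; the
identity-repeat rule (each identity used in a block's memory arrays
appears in 2–3 distinct trials, from a library of 60) is satisfied by a
greedy most-remaining-first assignment with random tie-breaks. Within a
trial, identities are distinct, and the foil is drawn from the library
excluding that trial's items.

## The generative model behind the simulator

The study's behavioural data are not public, so the package ships a
generative stand-in whose structure mirrors the three error sources the
paradigm is designed to separate. On each trial the simulated participant
identifies the target with condition-dependent probability
`p_ident[load, delay, block]`. A correctly identified report is then:

* anchored on the **target** with probability `1 - p_swap - p_guess`;
* anchored on a uniformly chosen **non-target** with probability
  `p_swap[delay, block]` (three-item trials only — misbinding requires
  something to misbind to);
* a uniform **guess** over the screen with probability `p_guess`.

Anchored reports add isotropic Gaussian noise with standard deviation
`sigma_deg` and are resampled until on-screen (truncation; clipping would
pile reports on the edges and bias every distance metric). Wrong
identifications produce a uniform report, which the scorer ignores — as in
the task, localization is only measured when the object was correctly
identified. The swap anchor is the non-target's true location, matching
the metric's definition against *original* array positions.

### Group presets and calibration

`default_group_presets()` provides control, asymptomatic-carrier and
symptomatic groups whose *expected* metrics approximate the published
group means (identification 91.7 / 89.9 / 81.8%; overall swap rates near
10.6 / 13.3 / 21.3% — the asymptomatic anchor is derived from the
published all-carrier and symptomatic values). The constants live in
`inst/extdata/group_presets.yaml`, not in code. Calibration was done once
against large simulated cohorts and the presets then frozen.

One compromise is worth knowing about: the model has a single,
load-independent `sigma_deg` per group. Published one-item errors (~2.4°)
imply a smaller noise SD than the three-item nearest-neighbour precision
(~3.7°) implies. We chose `sigma_deg` to match the nearest-neighbour
precision, because it feeds the swap classification; the consequence is
that simulated one-item and overall gross errors run roughly 10–15% above
the published means. Identification, swap rates and precision match
closely; gross error is approximate. Simulated cohorts therefore support
qualitative and calibration-level conclusions (orderings, effect
directions, recovery of generative parameters), not exact reproduction of
the study's statistics — which would require the unavailable human data.

Covariates (age, sex, NART, total hippocampal volume, TIV) are drawn from
group-specific Gaussian/Bernoulli distributions with means and SDs taken
from the published cohort tables where available (e.g. hippocampal volumes
5.8 ± 0.64, 6.0 ± 0.69 and 5.2 ± 0.55 cm³). Within carrier groups the
subject's realized swap probabilities follow a logit-linear link to
hippocampal volume: `volume_swap_slope` logits per cm³ above the group
mean volume, capped so the mixture stays valid. The default slope (−0.55
logit/cm³) was converted from the published square-root-scale regression
coefficient (−0.76 per cm³) at the all-carrier mean swap rate; the
published analysis reports only that linear fit, so any monotone link is
defensible and the logit keeps probabilities in range. The simulator does
not model learning mechanistically — block-dependent parameter tables
carry the block-2 improvement — and it ignores reaction times, eye
movements, and any real-data features beyond this mixture structure (no
heavy-tailed noise, no attentional lapses correlated across trials, no
spatial anisotropy). Passing tests show the *pipeline* is correct under
this model, not that real data behave this way.

## The chance correction

Reports far from the target can land near a non-target by luck, so raw
swap rates overstate misbinding, particularly for imprecise participants.
The published appendix formula for the correction is not available; the
package defines the null explicitly: for each eligible trial, the
non-target positions are redrawn `n_null` times by the same constrained
sampler *conditional on the realized target position*, preserving every
placement constraint and the trial's target geometry. The corrected rate
is the observed rate minus the mean null rate and is reported *unclamped*
(it may legitimately be negative, and truncation would bias group means
upward), together with a Monte-Carlo standard error combining the
binomial error of the observed rate and the between-replicate error of
the null mean; `clamp_zero = TRUE` truncates if required. The
`null_method` argument isolates this choice so the original appendix
calculation can be added without touching callers. Under a pure-guess
simulant the corrected rate is zero within Monte-Carlo error (this is a
tested property), and for target-anchored reports the null is nearly
silent because redrawn non-targets cannot fall within 4.5° of a report
that sits near the target.

## Inference choices

The published analysis reports t, z and F statistics from an appendix
model specification that is not available. The package implements the
simplest structure consistent with those statistics: per-subject (or
subject-by-cell) aggregation followed by covariate-adjusted linear models
— Gaussian on continuous outcomes, binomial on per-subject correct/total
counts. Behavioural contrasts adjust for NART and sex; volume models
adjust for age, sex and TIV, with per-group volume slopes and their
pairwise contrasts. Gross-error–volume associations are fitted on the log
scale so the slope exponentiates to a percent change per cm³; swap-rate
associations are square-root transformed first, matching the published
reporting scales. Whether the original trial-level models had random
subject effects is unknowable from the text; the aggregation level is
therefore explicit in the API (`summarize_subjects()` feeds every model)
rather than guessed. No multiple-testing correction is applied, as none
was in the study; every output says so.

Repeated-measures interaction tests (`factorial_interaction_test()`) run
on subject-by-cell means with an `Error(subject/within)` stratum
structure; with a single between factor and two groups the F statistic
reduces exactly to the squared two-sample t, which is tested.

BCa bootstrap intervals are computed in-package from 2000 replications:
bias correction `z0` from the proportion of bootstrap statistics below
the estimate (with a half-count for ties, clamped away from 0/1),
acceleration `a` from jackknife skewness, and type-6 quantiles of the
bootstrap distribution at the adjusted levels. With `z0 = a = 0` the
interval is exactly the percentile interval; degenerate data give a point
interval; group comparisons resample subjects stratified by group. The
implementation is cross-checked against `boot::boot.ci` in the tests.

## Numerical and degenerate-input conventions

* The swap boundary is inclusive (exactly 4.5° is a swap) and the
  inclusion criterion is inclusive (exactly 70% identification is
  included), both read directly from the stated thresholds.
* Empty denominators (no eligible trials in a cell) yield `NA` with the
  denominator reported, never a silent zero.
* Distance comparisons use a 1e-12 tolerance so exact-boundary constructed
  cases are classified deterministically.
* Rejection sampling failures name the violated constraint and the number
  of unplaced points; infeasible geometries fail at construction.
* All randomness flows through explicit seeds; cohorts are byte-for-byte
  reproducible, and per-subject streams are derived from the master seed
  so adding subjects does not reshuffle earlier ones.

## Problem sizes used in the shipped checks

The package's statistical validation uses sizes chosen to give stable
Monte-Carlo estimates: 10,000 arrays for the geometric sweeps; 2,000
trials × 500 null replicates for the pure-guess chance-correction check;
100 subjects per group for parameter recovery against a semi-analytic
oracle (independent rejection sampler + mixture algebra, with the volume
link integrated over the volume distribution); 1,000 replicates × B = 2000
for BCa coverage of a Gaussian mean at n = 50; 500 replicates at n = 30/30
for type-I calibration of the adjusted comparison; and 200 replicates of
40-carrier cohorts for sign recovery of the volume–misbinding slope. The
calibration-style checks share one session design across simulated
subjects, since the properties under test concern response-level
randomness, not design randomness.

## Known limitations

* A single load- and delay-independent noise SD per group (see the
  calibration note above).
* The chance-correction null is this package's definition; the original
  appendix calculation may differ in detail, though both are geometric
  nulls conditional on the target.
* Simulated covariates are independent Gaussians (no age–volume
  correlation, no NART–performance link), so covariate adjustment in
  simulations removes noise, not confounding.
* The swap classifier, like the original, undercounts misbinding in very
  imprecise participants whose swap-anchored reports fall outside the
  4.5° disc — visible here as the symptomatic group's raw swap rate
  sitting closer to its generative `p_swap` ceiling than the control
  group's.
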