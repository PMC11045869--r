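---
title: "Methods: smartwatch MET estimation, the synthetic trial generator, and the validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartwatch MET estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures the package implements, the
choices that were genuinely open and how they were resolved, what the
synthetic data generator does and does not emulate, and the numerical
conventions used throughout.

## The measurement problem

Wrist-worn accelerometers are a practical proxy for energy expenditure, but
the criterion measurement — indirect calorimetry, which derives METs from
inspired/expired gas volumes — is impossible outside supervised trials. The
package's estimator maps the watch's per-minute summary features to METs so
that minute-level intensity (sedentary, light, moderate, vigorous) can be
assessed in free-living studies. One MET is resting oxygen consumption
(3.5 ml O₂·kg⁻¹·min⁻¹); the conventional cut-points are SED ≤ 1.49 METs,
LPA 1.50–2.99, MPA 3.00–5.99, VPA ≥ 6.00, with MVPA = MPA ∪ VPA.

## Per-minute features

The watch samples each accelerometer axis at 2 Hz, giving 120 readings per
minute. For each axis the feature extractor computes the mean of the 119
*absolute* consecutive differences; `pa_avg` is the maximum over the three
axes and the arg-max axis is the dominant axis (ties broken x > y > z for
determinism). `pa_var` is the mean (divisor 119) of the squared deviations of
the dominant axis's absolute differences from `pa_avg`.

Absolute rather than signed differences are a deliberate choice: a signed
sum of consecutive differences telescopes to `(x[120] - x[1]) / 119`, which
measures net drift over the minute and is essentially zero for any periodic
movement. The absolute version measures the average magnitude of
acceleration change, which is what an activity feature must capture, and
makes `pa_avg` invariant under constant offsets (gravity) and homogeneous of
degree 1 under rescaling — properties the test suite asserts.

Steps are counted on the vector-magnitude signal: a centered moving average
(width 3 samples) smooths the magnitude, and local maxima exceeding the
smoothed signal's median by at least 0.15 signal units, separated by at
least 2 samples (1 s), are counted. The three constants are exposed as
arguments. At a 2 Hz sampling rate a step detector is inevitably coarse —
cadences at or near multiples of 120 steps/min alias to a constant and
cannot be seen, and the 1 s minimum spacing caps the count at 60/min. The
detector is deterministic and offset-invariant, which is what the pipeline
needs from it; it is not a validated pedometer.

Windows are half-open `[minute_start, minute_start + 60 s)`; partial windows
are rejected rather than padded, because a feature computed over fewer
samples is not comparable to the rest of the series.

## The synthetic trial generator

No raw data of this kind are publicly deposited, so the package generates
complete studies. The generator's defaults are the study conditions, not
tuning knobs:

* **Participants.** Demographics are truncated normal draws (±3 SD)
  calibrated to the reference populations: adults height 169.2 ± 7.2 cm,
  weight 61.7 ± 8.7 kg, age 21–34; children 160.5 ± 10.3 cm, 52.6 ± 12.5 kg,
  age 9–13. Gender is balanced; BMI is derived.
* **Protocol.** Seven sequential activities from sedentary to vigorous
  (sitting, standing still, slow walking, quick walking, stairs, jogging,
  running/rope-skipping); children skip jogging. Each trial lasts 14–16
  minutes (uniform — the protocol states the range but not a distribution).
* **Criterion METs.** Each trial draws a participant-level steady state from
  `Normal(mean, SD)` per activity (adults' sitting 1.01 ± 0.13 up to
  running 9.40 ± 3.74; children's table analogous), truncated below at
  0.5 MET as a physiological floor. Minutes 1–3 ramp linearly from rest
  toward the steady state; later minutes add `Normal(0, 0.1 × SD)` noise.
  The 0.1 factor attributes most of the published per-activity SD to
  between-participant variation, which is the plausible decomposition for
  steady-state activities; it is config-exposed because no data exist to
  identify it. The warm-up shape is likewise unidentifiable — it exists so
  that trimming the first three minutes is meaningful.
* **Accelerometry.** The generative link from METs to acceleration is
  invented by necessity (no such model is published): the dominant axis
  carries a sinusoid at the activity's cadence with amplitude
  `0.25 × (MET − 1)` (clamped at 0), the other axes carry half that, a 1 g
  offset sits on z, and all samples get Gaussian jitter (SD 0.02). This
  makes extracted `pa_avg` monotone in expectation in the true MET — the
  property the estimator needs — and resting minutes nearly flat. Cadences
  (100/110/105/130/155 steps/min for walking through running) are realistic
  for each activity and chosen so the sampled waveform is neither aliased
  away at 2 Hz nor erased by the step detector's smoothing.
* **Dropouts.** Independent Bernoulli non-wear (p = 0.02) and unstable-EE
  (p = 0.03) flags per minute; non-wear minutes lose their feature fields.
  "Unstable energy expenditure" has no published operational definition, so
  it is modeled as a flag rather than a mechanism.
* **Split.** `round(n × 0.7)` participants (half-up) train, the rest test —
  24 adults split 17/7, 18 children split 13/5. All of a participant's
  minutes inherit the assignment.

One master seed drives everything through derived per-stream sub-seeds, so a
study is bit-reproducible and adding participants does not reshuffle
existing ones.

What the generator does **not** emulate: VO₂ kinetics (minute METs are drawn
directly), breath-by-breath noise, posture transitions inside a minute,
device-specific quantization, and any systematic wear-position artifacts.
Passing tests on synthetic studies therefore demonstrate that the pipeline's
machinery is correct and well-calibrated under a monotone feature–MET link —
not that the published real-data accuracies transfer to any particular
device.

## The estimator

Class labels for training derive from the criterion METs via the cut-points,
collapsed to three classes (SED, LPA, MVPA). The five predictors are
`log(1 + pa_avg)`, `log(1 + pa_var)`, `log(1 + steps)`, gender (male = 1)
and BMI. `log(1 + x)` rather than `log x` because sedentary minutes have
exactly zero counts and features. Continuous features are standardized with
training-set constants stored in the model — standard practice for margin
classifiers; gender stays 0/1.

The classifier is a linear-kernel SVM, one-vs-rest with ties broken by the
larger decision value. The cost parameter C is grid-searched over
{0.01, 0.1, 1, 10, 100} by 5-fold cross-validation with folds grouped by
participant, scored by macro accuracy (mean per-class recall). Grouped folds
mirror the participant-level train/test split: minutes within a participant
are strongly dependent, and row-wise folds would leak identity and inflate
the CV score. The published procedure names only "grid search" and
"fivefold"; the grid, the scoring metric and the grouping are this package's
choices. Where the SVM stage and the regression stage each use the features
is also ambiguous in the source description ("gender, BMI were used to
estimate METs"); both stages use all five predictors here, which is the
conservative reading.

One OLS regression per *true* class maps features to METs. Training on true
classes avoids propagating classifier error into the regression fit;
applying by *predicted* class at inference is forced (the truth is unknown
then). Within a single intensity class a feature can be constant (sedentary
minutes all have zero steps); the fit pivots such columns out and reports a
zero coefficient. Estimates are clamped at 0.5 MET because an affine model
can extrapolate below the physiological range, then categorized by the
cut-points. The boundary semantics are: SED iff MET ≤ 1.49, LPA iff
MET < 3.00, MPA iff MET < 6.00, else VPA — a total monotone partition of
(0, ∞).

Models serialize to versioned JSON with coefficients as 17-significant-digit
strings; plain JSON numbers round-trip doubles approximately but not
bit-exactly, and the save/load contract here is exact reproduction of every
estimate.

## The validation battery

Evaluation refuses test sets sharing participants with training. Each minute
gets an estimated MET; then:

* **Classification.** Three one-vs-rest tasks — SED (positive ⇔ true
  MET ≤ 1.49), MVPA (≥ 3.00), VPA (≥ 6.00). Sensitivity and specificity are
  computed at the categorized-estimate operating point with Wilson 95%
  intervals; Youden's J = sens + spec − 1. AUC uses the *continuous*
  estimated MET as score (negated for SED so that higher = more positive):
  a binary prediction alone cannot trace a ROC curve, so the continuous
  score is the only coherent reading. AUC is the concordance (trapezoidal)
  estimator with ties counted ½; its interval and variance come from
  DeLong's method. Adults and children are independent samples, so their
  AUCs are compared with an unpaired z-test on the DeLong variances.
* **Error.** MAE, MAPE (percent) and RMSE, pooled over minutes, each with
  the SD of its per-minute components, plus per-participant means ± SD. The
  "±" companion of a pooled RMSE has no standard definition; the package
  labels explicitly what it reports (SD of per-minute root squared errors,
  and separately the per-participant spread).
* **Agreement.** Bland–Altman with differences `estimated − true` (the
  direction is configurable; conventions differ across publications), bias =
  mean difference, limits = bias ± 1.96 × sample SD. ICC(2,1) — two-way
  random effects, absolute agreement, single measures — computed from the
  mean-squares decomposition; the two-way absolute-agreement form is the
  defensible choice when a fixed estimator is compared against a criterion
  and systematic shifts should count against agreement. Spearman's rho with
  the asymptotic t-approximation p-value.

Rounding to 2 decimals happens only at display time; all stored values are
full precision.

## Numerical conventions and degenerate inputs

* Feature extraction equals a direct-loop reference to 1e-12; the OLS step
  equals an explicit normal-equations solve to 1e-8; ICC matches a
  hand-computed variance-components fixture to 1e-10 (all asserted in the
  test suite against independent oracles).
* Single-class truth makes sensitivity/specificity/AUC undefined: error,
  not NA. Constant series make Spearman and ICC undefined: error.
* A zero-variance feature column standardizes with scale 1 instead of 0.
* Exact decision-value ties in the one-vs-rest SVM resolve to the first
  class in SED, LPA, MVPA order; they occur only on degenerate data.
* All CLI outputs are pure functions of config + seed (no timestamps), so
  reruns are byte-identical; provenance (config hash, seed, package
  version) is written beside every output.

## Problem sizes used in the shipped checks

The test suite exercises studies of 6–10 participants per group and the
calibration check uses 50 participants' MET series per activity; the
reproduction script (`scripts/acceptance.R`) runs the full protocol sizes,
24 adults and 18 children. These sizes give stable statistics for every
metric while keeping the default runs quick on a laptop.

## Known limitations

* The feature–MET link in the generator is monotone by construction, so
  synthetic accuracies are optimistic relative to real wrist data with
  posture artifacts and device noise.
* The step detector is bounded by the 2 Hz sampling rate and is not a
  cadence estimator.
* The acceleration unit is arbitrary-but-consistent; published feature
  magnitudes cannot be matched because the source device's units and
  encodings are not documented.
* Adult and child models do not transfer and are never mixed; the package
  trains and validates them separately by design.
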