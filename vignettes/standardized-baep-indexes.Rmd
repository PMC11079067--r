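---
title: "Standardized intraoperative BAEP indexes: model, simulator and evaluation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized intraoperative BAEP indexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baepstd)
```

## The problem

During resection of vestibular schwannomas and other cerebellopontine-angle
tumours, the cochlear nerve is monitored with brainstem auditory evoked
potentials (BAEPs): click-evoked scalp potentials averaged over thousands of
sweeps, whose waves I–V index successive stations of the auditory pathway.
The canonical injury signs are prolongation of the wave-V latency and
reduction of the wave-V amplitude on the operated (affected) side. BAEPs are
tiny (0.1–0.5 μV), so the averaged indicators are contaminated by
interference that has nothing to do with the nerve at risk: anaesthetic
depth, temperature, electrical noise, electrode drift. Crucially, most of
this interference is *common-mode* — it affects both ears' recordings
together — whereas surgical injury affects the operated side only.

`baepstd` implements the referencing idea that exploits this asymmetry: when
both ears are recorded intraoperatively and epochs are paired synchronously
(recording interval ≤ 3 min), the healthy side can serve as a
contemporaneous reference that cancels the shared interference.

## The indexes

For any indicator (a latency `La-…` in ms or an amplitude `Am-I`, `Am-V` in
μV), with `a` the affected-side and `h` the healthy-side value of a
synchronous pair:

* **STI** (standardized index) `= a / h − 1`, dimensionless. If an
  interference factor `c > 0` multiplies both ears, `STI(ca, ch) = STI(a, h)`
  identically — the motivating algebraic property, and a property test in the
  suite.
* **D** (intraoperative difference) `= a_post − a_pre`, the affected-side
  change from the pre-resection to the post-resection phase, in the
  indicator's units.
* **STD** (standardized difference) `= D − (h_post − h_pre)`, which removes
  any drift *added* equally to both ears between the phases.

A constant "normal reference value" can be multiplied onto the STI to obtain
a standardized value in physical units (`standardized_values()`); since it
is a constant it carries no information and the dimensionless STI is used
throughout the analysis.

Pre-resection means epochs recorded from the start of surgery until tumour
exposure; post-resection means epochs between complete resection and the end
of surgery. Epochs acquired during active resection are excluded from both
phases. One representative value per phase and side is required; the package
uses the per-indicator **median** over the phase's pairs (the mean is
available), because interference produces occasional outlier epochs. An
indicator absent (e.g. a disappeared wave) in more than half of a phase's
pairs is treated as absent, and absence propagates into the indexes rather
than being imputed: a vanished wave V is qualitatively different from a
small one, and downstream regressions use complete cases with the analysed
`n` reported.

### Pairing

Streams from the two ears are matched greedily: the globally closest
remaining affected/healthy pair with the same phase and interval ≤ 180 s is
accepted, each epoch used at most once. The 3-minute criterion is read as
inclusive (an interval of exactly 180 s pairs). Greedy matching rather than
optimal bipartite assignment is a deliberate simplification: real binaural
streams are near-alternating, where greedy and optimal coincide; the
matching is isolated in `pair_streams()` and swappable. Ties in the interval
are broken toward the earlier epoch, making the matching deterministic.

## The synthetic cohort generator

No public BAEP cohort with binaural intraoperative streams exists, so the
package ships a first-class simulator (`simulate_cohort()`) whose defaults
encode the study conditions the analysis assumes:

* **Timeline.** 240-minute surgeries; one averaged epoch per ear every 168 s
  (2000 sweeps at an 11.9 Hz click rate), the two ears' grids interleaved
  with a 60 s offset; 5% of epochs lost at random, so the ≤ 3 min pairing
  rule is exercised non-trivially. Tumour exposure and complete resection
  fall near 25% and 75% of the surgery.
* **Latent cochlear function** `f ∈ [0, 1]` drives everything patient-
  specific: the preoperative level, a per-patient injury depth drawn
  `Uniform(0, 0.62)`, and a linear decline between resection start and end.
* **Injury effects (affected side only).** Wave-V latency gains
  `0.6 ms × (1 − f)`; wave-V amplitude is scaled by `1 − 0.8 (1 − f)`.
  Wave I, which arises peripherally in the cochlear nerve, is left
  unaffected, so the simulated injury is retrocochlear.
* **Common-mode interference.** Two multiplicative log random walks per
  patient (one for latencies, sd 0.02 over the surgery; one for amplitudes,
  sd 0.25), applied identically to both ears — exactly the component the STI
  cancels. Per-patient global scale factors (log-sd 0.02 / 0.20) model
  inter-individual variability that also cancels; a small interaural
  asymmetry (log-sd 0.05) models electrode/anatomy differences that do
  *not* cancel and bound the achievable index precision.
* **Measurement noise.** Additive per-epoch noise of 0.05 ms on latencies
  and 0.02 μV on amplitudes.
* **Audiometry.** WRS is a logistic in `f` rescaled to hit 20% at `f = 0`
  and 95% at `f = 1` (slope 6, midpoint 0.5); PTA falls affinely from 85 dB
  to 15 dB; test–retest noise 3% / 4 dB; outputs clamped to WRS ∈ [0, 100],
  PTA ∈ [0, 120]. Under the AAO-HNS thresholds below, hearing preservation
  is equivalent to WRS ≥ 50, and the noise-free WRS crosses 50% at
  `f* ≈ 0.44`. Preoperative `f` is drawn above or below `f*` with
  probability 0.66 — the preoperative HP rate of the 127-patient series the
  defaults mirror — and the `Uniform(0, 0.62)` injury depth puts the
  postoperative HP probability among preoperatively preserved patients near
  0.45, mirroring the same series (38/84). The healthy ear's `f` is drawn
  in [0.9, 1] and does not change with surgery.

Every stochastic draw is made unconditionally and scaled by its standard
deviation, so two configurations differing only in a noise scale share all
other draws under the same seed. This is what makes the common-mode
component *separable by regeneration*: simulating the same seed with
`common_mode_sd = 0` and dividing epoch-wise recovers the stored latent walk
exactly — a test in the suite. Each patient's latent state (function levels,
injury, both walks) is kept in the record for exactly this kind of
diagnostic.

**What the simulator does not emulate:** real wave morphology variation,
non-stationary or ear-asymmetric interference, electrode failures that
corrupt rather than delete epochs, audiogram frequency structure, or any
dependence of injury on tumour size and approach. Passing tests therefore
show that the *pipeline arithmetic and inference machinery* behave as
designed under the stated noise model — not that the indexes achieve any
particular accuracy on real recordings.

## The waveform layer

The feature tables can come from any averaging system; the package also
synthesizes averaged traces from indicator vectors and measures them back
(`synthesize_waveform()` / `extract_wave_features()`), as a round-trip
fixture for the measurement conventions. Each wave is a positive Gaussian
lobe at its latency followed by a matched negative lobe 4 sd later, scaled
so peak-to-trough equals the amplitude; morphology beyond "positive peak,
then trough" is not modelled because only that is measured. Numerical
choices: lobe sd 0.07 ms; synthesis at 100 kHz so that the 0.0025 μV
amplitude quantization, not the sample grid, limits resolution; residual
noise sd scales as `noise_sd/√averages`. Extraction takes the maximal
positive sample per canonical search window (I 1.2–2.2, II 2.3–3.3,
III 3.4–4.5, IV 4.6–5.4, V 5.4–6.8 ms, configurable), using the centre of a
quantization-flattened plateau and resolving distinct equal peaks to the
earlier one; the trough search stops at the next wave's window (an
interpretation — the alternative of crossing into the next window is
ambiguous in common usage), and a peak-to-trough below 0.05 μV declares the
wave absent ("wave disappearance"; no standard threshold exists, the value
is configurable). A wave's absence is a value, not an error.

## Hearing outcomes

Audiometry is classified with the standard AAO-HNS (1995) thresholds:
A (PTA ≤ 30 dB, WRS ≥ 70%), B (PTA ≤ 50 dB, WRS ≥ 50%, not A),
C (PTA > 50 dB, WRS ≥ 50%), D (WRS < 50%); hearing preservation (HP) is
class A–C, equivalently WRS ≥ 50%. The classes partition the audiometry
space (property-tested on a grid). `outcome_table()` reports preoperative
percentages over all patients and postoperative percentages over the
preoperatively preserved subset — the denominators under which published
class counts of this kind reproduce — rounding percentages half-up to one
decimal as clinical tables do.

## The evaluation battery

* **Univariate logistic screen** (`univariate_logistic()`): ML fit of
  `logit P(HP) = β₀ + β₁x` with Wald OR, 95% CI and p (Wald rather than
  profile likelihood, matching mainstream clinical software). Degenerate
  inputs are explicit results, not crashes: constant predictors return
  OR 1 / p 1 with status `degenerate`; complete separation sets status
  `separation`.
* **Stepwise multivariate model** (`multivariate_stepwise()`): candidates
  with univariate p ≤ 0.05 enter; backward elimination removes the largest
  Wald p until all survivors are ≤ 0.05. Backward was chosen as the default
  because it starts from the model the screen justifies; forward selection
  is provided. Aliased duplicates are dropped up front.
* **ROC** (`roc_analysis()`): AUC as the midrank Mann–Whitney statistic
  (ties half-counted), identical to the trapezoidal area; orientation is
  fixed (higher score ⇒ positive call) and the AUC reported as-is, so a
  protective indicator shows AUC < 0.5 rather than being silently flipped.
  The cutoff maximizes Youden's J over observed score values (the usual rule
  when a cutoff is reported without one), with near-ties (within 1e-9)
  resolved to the lowest threshold.
* **Paired AUC comparison** (`compare_aucs()`): DeLong's placement-value
  test, the standard paired test when no method is named. A zero-variance
  difference (identical or rank-equivalent scores) returns p = 1 exactly.
* **Group comparisons** (`group_comparisons()`): paired t-tests for paired
  two-group contrasts and one-way ANOVA across ≥ 3 groups, with guarded
  degenerate cases (constant differences → t = 0, p = 1; identical group
  means → F = 0, p = 1).

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated data:
structural tests use 3–25 patients with 45–90 minute surgeries; calibration
checks use one 127-patient cohort with 1000 noise predictors (null type-I
rate) and 500 patients (binomial HP-rate check); the headline comparison of
standardized vs raw wave-V amplitude uses 100 seeded replicates of 127
patients under amplitude common-mode sd 0.5 — a strong-interference
condition relative to the 0.8 fractional injury effect — and compares median
AUCs. These sizes were chosen to estimate each quantity to well inside its
assertion margin.

## Known limitations

* Greedy pairing can differ from optimal matching on pathological timing
  patterns; yields are logged per patient because pairing loss is the
  pipeline's main attrition point.
* Complete-case handling of disappeared waves discards exactly the patients
  with the most dramatic injury; any real deployment should report how many
  such patients exist (the tables carry `n` per model).
* The Wald-p stepwise procedure inherits the known instabilities of stepwise
  selection; it is provided because it is the procedure such clinical
  analyses use, not as a recommendation.
* The simulator's linear injury ramp and single latent function variable are
  the simplest mechanism producing distinct pre/post phases; they are not a
  physiological model of cochlear nerve injury.
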