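---
title: "Methods: simulation and analysis of cuff-occlusion optical spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of cuff-occlusion optical spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its model

Dynamic vascular optical spectroscopy (DVOS) monitors hemoglobin dynamics in
foot tissue while a thigh cuff manipulates venous outflow. The protocol is
five contiguous one-minute phases sampled at 2.56 Hz: baseline (< 5 mmHg),
60-mmHg occlusion (venous outflow blocked, arterial inflow preserved),
recovery, 100-mmHg occlusion (venous plus partial arterial), recovery.
During venous occlusion arterial inflow keeps filling the limb, so total
hemoglobin \(\mathrm{HbT} = \mathrm{HbO} + \mathrm{HbD}\) pools at a rate
governed by distal arterial patency — the physiological signal that separates
limbs with peripheral arterial disease (PAD) from healthy ones.

Light at 670/780/808/850 nm from each patch traverses the tissue to two
photodetectors. The package relates concentration changes to measured
intensities through the modified Beer–Lambert law,

\[\Delta OD(\lambda, t) \;=\; \bigl[\varepsilon_{HbO}(\lambda)\,\Delta HbO(t)
 + \varepsilon_{HbD}(\lambda)\,\Delta HbD(t)\bigr]\; L \cdot \mathrm{DPF},\]

with \(\Delta OD = -\log_{10} I(t)/I_{\mathrm{baseline}}\), source–detector
distance \(L\) (default 3 cm) and a fixed differential pathlength factor
(default 4.0). The clinical system reconstructs concentrations with a
PDE-constrained multispectral algorithm whose equations are not public; this
package deliberately substitutes the Beer–Lambert inversion — the standard
desk-scale surrogate — because every downstream feature depends only on
*relative* concentration dynamics, which the two approaches share. The
substitution is a documented modelling choice, not an approximation claim
about absolute quantification. Inversion solves the per-time-point least
squares system across available wavelengths per detector; the two detectors'
traces are averaged *after* inversion (how the device merges detectors is
unstated; averaging is our documented choice). Because \(\Delta OD\) is
referenced to each channel's own baseline mean, channel gains cancel exactly,
a property the test suite asserts.

## Preprocessing

* **SNR screen.** Channel quality is the baseline-phase mean of the raw
  intensity divided by its SD. Channels with SNR < 4 are excluded (strict
  inequality: exactly 4 is retained). A recording whose survivors span fewer
  than two distinct wavelengths is flagged unreconstructable, not repaired.
* **Filtering.** A 2nd-order low-pass Butterworth (cutoff 0.51 Hz) is applied
  to the retained raw intensities before inversion. We filter forward and
  backward (zero phase): a causal pass would delay the early-occlusion rise
  and bias the interval-slope features, whereas the double pass leaves slope
  timing unchanged (the suite checks a zero cross-correlation lag on ramps).
  Edges use odd-reflection padding with steady-state initialisation so the
  768-sample records carry no start-up transient; the double pass squares the
  magnitude response, giving amplitude 1/2 at the (prewarped) cutoff.
* **Motion.** The study excluded motion-corrupted recordings without defining
  a detector; `flag_motion()` (robust z-score spikes + rolling-median steps)
  exists to exercise that QC path and is off in the default generator.

## The four hemodynamic parameters

For each occlusion phase, from the reconstructed trace:

* \(\Delta\mathrm{HbO}\): maximum HbO during occlusion minus the mean over
  the 5 s before inflation (occlusion-only search; the definition says
  "during venous occlusion").
* **HF** (hemoglobin flow): the first 30 s of occlusion are split into six
  half-open 5-s windows; an ordinary least-squares slope is fitted in each,
  and HF is the maximum. Negative maxima are not clipped.
* **VO₂**: the same six-window maximum applied to HbD, converted to
  mL O₂/100 mL tissue/min by \(4 \times 0.0224 \times 60 / 10 = 0.5376\)
  per (µmol/L/s) — four O₂ per hemoglobin tetramer, 22.4 mL/mmol molar
  volume, per-minute and per-100-mL scaling. The factor is re-derived by an
  independent dimensional-analysis oracle in the tests before use. The
  source text states the 30-s window for VO₂ without restating the
  six-interval scheme; we reuse the same scheme for consistency and noise
  robustness.
* **Tp** (plateau time): time for HbT to pass from 90% of its occlusion
  maximum (rising) to 90% of that maximum after deflation (falling), both
  crossings linearly interpolated between samples (nearest-sample timing
  would be quantised at 0.39 s). First-crossing semantics are used on the
  falling side; a signal that never falls below the level is truncated at
  recovery end and flagged.

**The HF reporting scale.** The published group statistics for HF are only
internally consistent if HF denotes the HbT *rise over the steepest 5-s
interval* (µmol/L per interval): a per-second slope of the printed magnitude
would imply an intra-interval HbT rise larger than the printed total HbT
excursion for three of the four group/pressure combinations. `hemoglobin_flow()`
therefore returns the literal maximal slope in µmol/L/s, and
`extract_features()` reports `hf` multiplied by the 5-s window — the scale on
which the calibration table, all group statistics, and the acceptance report
operate. ΔHbT (the analogous HbT rise) is computed alongside for the
redundancy analysis but is never a model input, since it is collinear with
ΔHbO.

Tp presumes baseline-referenced traces: a 90%-of-maximum level is not
invariant under adding an arbitrary constant, so shift invariance is asserted
for ΔHbO/HF/VO₂ only, and scale equivariance for all amplitude features.

## Synthetic cohort: the stated world

No recordings are publicly available, so the package ships a generator whose
defaults *are* the published cohort: 118 PAD and 118 non-PAD diabetic
subjects, covariates drawn from the printed group moments and proportions,
and per-subject feature targets drawn from the printed mean ± SD of each of
the eight parameters.

* **Truncated-normal re-standardisation.** Printed moments are means ± SDs;
  sampling truncates at physiologic bounds (age ≥ 18, BMI ≥ 15, durations
  ≥ 0, features above small device-resolution floors of 0.2 µmol/L, 0.05
  µmol/interval and 0.002 mL O₂/100 mL/min; Tp in [5, 50] s so a plateau is
  constructible and washout completes inside the recovery). The underlying
  (µ, σ) are solved so the *truncated* moments equal the printed ones
  (lower-bound-only cases reduce to a monotone one-dimensional root; two-sided
  cases use a damped fixed point), keeping cohort moments calibrated despite
  truncation.
* **Zero-inflated hypertension duration.** The printed duration (5.4 ± 6.9 y
  non-PAD) has SD > mean, impossible for a positive-only truncated normal; it
  reflects the ~45% of subjects without hypertension. Duration is therefore
  hypertension-indicator × conditional truncated normal with the conditional
  moments solved so the *overall* mean/SD match, and the indicator doubles as
  the antihypertensive-medication covariate (their printed proportions
  coincide).
* **Severity factor.** One latent standard-normal severity per subject loads
  (default 0.6) on every standardised feature through a Gaussian copula, so
  marginals stay exactly calibrated while parameters correlate positively —
  the published ΔHbT–ΔHbO correlation (r > 0.7) then *emerges* from the
  additive identity rather than being imposed. The same factor spans both
  pressures; the within-subject 60/100-mmHg correlation is unreported, and
  this is flagged as an assumption.
* **Trace construction.** Targets become traces by a piecewise-linear
  skeleton smoothed with a 3-sample moving average (analytically controllable,
  unlike exponentials): HbT rises at the HF-implied rate for 5.8 s (one full
  slope window plus smoothing guard), decelerates through two segments to its
  peak at deflation — held on a short 1.6-s shelf so smoothing cannot erode
  the maximum — then falls at the rate that realises the Tp target, then
  washes out to baseline before the next phase. HbD rises at the VO₂-implied
  rate for 12 s, declines slightly (reconciling a positive early slope with
  the published slight late decrease in non-PAD), and is steered so the
  end-occlusion HbO level equals the ΔHbO target, making HbO's occlusion
  maximum the target exactly. HbO ≡ HbT − HbD at every sample. When a
  sampled combination admits no such concave shape (small ΔHbO or short Tp
  against a large HF-mandated ramp), the builder falls back to a late-ramp
  and then a late-ramp-with-dip morphology; with the fallbacks no rejection
  was observed in 6000 sampled target vectors, and a residual redraw guard
  remains. A noiseless constructed trace round-trips through extraction to
  within 5% (Tp: within 2 samples), which is what makes every later stage
  testable.
* **Measurement noise.** The paper specifies no noise model. Defaults are
  0.5% multiplicative Gaussian intensity noise (baseline SNR ≈ 200,
  representative of channels *retained* by the SNR ≥ 4 screen) and a
  per-channel random linear drift of SD 0.1%/min. These were fixed from the
  instrument context before any acceptance quantity was measured. Degraded
  channels (`low_snr_fraction`) and motion artifacts exist only to exercise
  QC.

**What a green test does not establish.** The generator reproduces marginal
group distributions, one global severity correlation, and the trace
morphology — not spatial structure across angiosomes, cardiac/respiratory
pulsation, baseline physiological drift, skin-tone or adiposity optics, or
any covariate–hemodynamics coupling beyond group membership. End-to-end
classification metrics on synthetic cohorts therefore validate the
*machinery* (models, folds, pooling, thresholds), not the clinical effect
size; cohort-specific published values (odds ratios, AUCs, confusion counts)
are display formats here, not reproduction targets.

## Statistics

Group comparison uses the Mann–Whitney U test (exact enumeration when both
groups have ≤ 8 subjects — which doubles as the small-sample oracle —
otherwise the tie-corrected, continuity-corrected normal approximation) at
the Bonferroni threshold 0.05/8 = 0.00625. Identical constant samples return
p = 1 with a degeneracy flag. Spearman's rho uses midranks with a
t-approximation.

Adjusted association and classification use one binary logistic model per
parameter with covariates age, diabetes duration, hypertension duration, sex,
BMI, and smoking status; Wald 95% CIs on the odds-ratio scale. Separation is
detected scale-freely (SD-standardised coefficients, non-convergence, or
all-extreme fitted probabilities) and flagged with results withheld rather
than silently reported. Performance is evaluated by stratified fivefold
cross-validation: per-class fold counts differ by at most one and leftovers
rotate across folds so overall fold sizes are maximally even (118 + 118
yields 48/47/47/47/47). Out-of-fold probabilities are pooled for the ROC,
AUC, and the confusion matrix at the fixed threshold 0.50; a probability of
exactly 0.50 is classified PAD (the source states both ≥ and ≤ conventions
at the boundary; ≥ is adopted). Fold-local AUCs and threshold metrics are
also summarised as mean ± SD, since whether published per-fold AUCs are
fold-local or pooled-restricted is unstated — both views are emitted. The
trapezoidal AUC equals \(U/(n_1 n_2)\) exactly, and the suite enforces this
cross-module identity on every tested input. A sensitivity analysis adds
statin/antiplatelet/antihypertensive indicators; fold assignments depend only
on labels and seed, so they are unchanged by construction.

## Numerical and interface choices

* Butterworth coefficients come from the bilinear transform with prewarped
  cutoff; the design was cross-checked against an independent reference
  implementation during development and against the analytic magnitude
  response in the tests.
* Concentrations are µmol/L changes from baseline throughout (the printed
  "µmol" is read as µmol/L, as the companion ΔHbT values are printed); the
  µmol↔mmol factor of the inversion is covered by a dimensional test.
* ΔOD uses base-10 logarithms; a natural-log mode exists behind a flag and
  the two are never mixed within a run.
* Trace files are self-describing columnar text at 9 significant digits;
  re-reading and re-writing reproduces the file byte for byte.
* All randomness flows from a single integer seed per operation
  (`generate_cohort()`, `stratified_kfold()`, `run_config()`), making full
  pipeline runs bitwise reproducible.

## Known limitations

Tp extracted from noisy traces is biased low relative to its generative
target (noise advances the first falling crossing and inflates the observed
maximum); the bias affects both groups alike and Tp is the weakest
discriminator here as in the published analysis. The Beer–Lambert surrogate
does not quantify absolute concentrations. The generator's feasibility
fallback morphologies (late ramp, mid-occlusion dip) are constructive
devices for tail target combinations, not physiological claims.
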