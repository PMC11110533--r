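---
title: "Methods: prefrontal fNIRS preprocessing and glucose association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prefrontal fNIRS preprocessing and glucose association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scientific setting

Continuous-wave functional near-infrared spectroscopy (fNIRS) measures
attenuation of 760 and 830 nm light between scalp source-detector pairs.
Because oxy- and deoxyhemoglobin (HbO, HbR) have distinct extinction
spectra at these wavelengths, changes in optical density (OD) can be
inverted, via the modified Beer-Lambert law (MBLL), into chromophore
concentration changes in cortex. The package studies a specific question:
whether prefrontal HbO dynamics track blood glucose as a subject moves from
a fasted state through a glucose-loaded excursion, and whether simple
time-series features of HbO support non-invasive glucose estimation.

The design the package emulates is a two-state session per subject: a
10-minute fasting baseline, then a glucose load followed by 60 minutes of
continuous monitoring, with intermittent fingertip reference glucose
values. Fifteen subjects, a 21-channel prefrontal montage at 30 mm
source-detector separation.

## Synthetic cohort generator

No human recordings ship with the package; `generate_cohort()` produces
fully synthetic cohorts whose statistical structure matches that design,
with complete ground truth for validation:

* **Glucose curve** — a constant fasting level (5.0 ± 0.4 mmol/L between
  subjects), a linear rise after the load to `fasting + delta`
  (delta 3.0 ± 0.5 mmol/L) at a peak 30 ± 5 min post-load, then exponential
  decay (tau = 15 min) to a plateau at `fasting + 0.3 delta`. These values
  are ordinary ranges for an oral glucose excursion in healthy adults; the
  curve family is piecewise because only the qualitative shape (stable,
  rise to peak, partial return) is constrained.
* **Hemodynamic coupling** — on five "coupled" channels (7, 12, 15, 18, 19)
  HbO follows `beta * (G(t) - G_fast)` with beta drawn per subject
  (0.15 ± 0.03 uM per mmol/L); the remaining 16 channels have beta = 0.
  With a 3 mmol/L excursion this yields sub-micromolar HbO shifts, the
  magnitude regime of slow metabolic fNIRS responses. HbR is generated as
  `-0.3 * HbO` plus independent noise, the canonical anti-correlated
  hemodynamic pattern.
* **Physiological noise** — cardiac (1.1 Hz, 0.08 uM), respiratory
  (0.25 Hz, 0.05 uM) and Mayer-wave (0.1 Hz, 0.04 uM) sinusoids with random
  phases, plus white noise (0.05 uM). Frequencies are the standard fNIRS
  nuisance triplet.
* **Optics** — the forward MBLL maps HbO/HbR to dual-wavelength intensity
  using tabulated extinction coefficients (760 nm: 0.586 / 1.5485; 830 nm:
  0.974 / 0.6930, per mM per cm), DPF 6 and d = 3 cm, with baseline
  intensity 0.5 (inside the pruning range).
* **Motion artifacts** — Poisson-timed exponential-decay spikes
  (0.5/min, 5-20% of baseline intensity, tau 0.5-2 s) and step baseline
  shifts (0.1/min, 1-5%), applied to all channels as head motion is, and
  logged as ground truth.

Everything is driven by one root seed through derived per-subject and
per-stage substreams: identical configurations are bit-identical.

What the generator does **not** emulate: photon transport and layered
tissue, optode-coupling drift, serial correlation of measurement noise,
inter-channel anatomical correlation, and any physiological nonlinearity in
the glucose-HbO relation. Passing tests therefore demonstrate that the
pipeline recovers the *statistical structure it encodes* — linear coupling
confined to known channels under realistic noise — not that real cortex
behaves this way.

## Preprocessing chain

`run_preprocessing()` applies, in order: channel pruning (mean intensity in
[1e-2, 1] and SNR = mean/sd >= 2 at both wavelengths), OD conversion
`-log10(I/Iref)`, window-based motion-artifact detection, wavelet motion
correction, zero-phase band filtering, MBLL inversion, and
correlation-based signal improvement (CBSI: `alpha = sd(HbO)/sd(HbR)`,
`HbO' = (HbO - alpha HbR)/2`, `HbR' = -HbO'/alpha`).

Numerical choices worth recording:

* **OD reference.** The conversion defaults to the recording's temporal
  mean. For session analysis, `preprocess_subject()` concatenates the
  fasting and glucose recordings and references OD to the *fasting
  baseline*. A per-state mean reference would, by construction, remove the
  between-state concentration offset that both the channel t-tests and the
  glucose association measure; baseline referencing is the standard
  "change from baseline" convention and preserves it.
* **Filter band.** The band filter is a forward-backward Butterworth
  cascade (3rd-order low-pass plus optional high-pass), numerically robust
  at normalized cutoffs of 1e-3. The conventional hemodynamic band
  0.01-0.1 Hz is implemented and verified (gain 0.985 at 0.05 Hz, 8e-5 at
  0.5 Hz, 0.011 at DC on 600-s fixtures). The *pipeline default*, however,
  is a pure 0.1 Hz low-pass (`band = c(0, 0.1)`): the glucose-coupled HbO
  trend evolves over 10-30 minutes (below 0.001 Hz), and a 0.01 Hz
  high-pass attenuates it by roughly (f/0.01)^3 — i.e., removes the signal
  of interest essentially completely. The 0.01-0.1 Hz band remains one
  argument away for task-evoked work.
* **Wavelet correction.** No discrete-wavelet package is part of the
  package's dependency stack, so a periodized orthonormal Daubechies-2 DWT
  is implemented internally (perfect reconstruction to 1e-10; coefficient
  energy equals signal energy). Detail coefficients outside the Tukey
  fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` at each level are zeroed.
  Decomposition depth defaults to `floor(log2(fs / 0.01))`, capped so the
  coarsest level keeps at least four coefficients; series are extended by
  tail reflection to a dyadic multiple and truncated after reconstruction.
  On fixtures this attenuates a 2-s spike by 87% while changing the RMS of
  an in-band 0.05 Hz sinusoid by under 10%. Step artifacts are only
  partially corrected — their residual lives in the approximation
  coefficients, which are never thresholded — a known limitation shared by
  coefficient-thresholding correctors.
* **Artifact masks** are informational: masked segments are corrected,
  never deleted, so downstream windows stay contiguous.
* **CBSI** skips (and flags) channels with zero-variance HbR rather than
  dividing by zero.

## Channel selection

Per channel, a Welch two-sample t-test compares fasting versus
glucose-state HbO "samples", where a sample is a per-subject 60-s window
mean. Two conventions need justification:

* **Tail convention.** The default one-sided p-value `P(T <= -|t|)` is the
  convention under which published channel tables of (t, p) pairs such as
  (-1.91, 0.0278) or (1.66, 0.0483) are internally consistent at large
  degrees of freedom; a two-sided option is exposed.
* **T-test window length.** The t-test uses 60-s windows rather than the
  600-s feature windows. With baseline-referenced OD, a fasting-length
  window mean is pinned near zero *by construction*, so at one window per
  state the fasting group would have artificially degenerate variance and
  the test statistic would explode on null channels. Minute-scale windows
  restore genuine within-state spread to both groups; empirically the five
  coupled channels are recovered with ~0-1 false positives out of 16 null
  channels at alpha = 0.05.

Selection is raw `p < 0.05` in ascending channel order (no multiplicity
correction, matching the analysis the package reproduces); a
Benjamini-Hochberg option exists but is off by default.

## Features

Ten features per 600-s window of channel-averaged HbO (population,
divide-by-count standard deviations throughout, matching the divide-by-T
definition of the basic deviation feature):
mean; standard deviation; mean and standard deviation of the first
difference; mean and standard deviation of the second difference; maximum;
peak-to-peak; energy `sum(x^2) dt`; and energy entropy
`-sum(x^2 ln x^2) dt` with `0 ln 0 = 0`, in nats. Integrals are rectangle
sums with the sampling step. Windows shorter than four samples are
rejected (second differences and their spread need them). The energy
entropy is applied to raw squared amplitude as defined; a normalized
Shannon-entropy variant is available behind a flag. Whether features should
be computed per channel or on the channel-averaged signal is not dictated
by the design; channel-averaging is the default because the downstream
association and models pool channels anyway.

A note on magnitudes: `-x^2 ln(x^2)` is increasing only for `x^2 < 1/e`.
With sub-micromolar HbO changes (the regime both of the generator and of
slow metabolic responses), squared amplitudes stay below that knee, so
energy and energy entropy rise together with glucose-coupled signal — the
positive-correlation pattern the association stage expects.

## Decreasing-rule PCA

Plain PCA eigendecomposes the centered training scatter
`Pi = sum (x - xbar)(x - xbar)^T`. The decreasing rule re-scores each
eigenvector `C_k` with the Fisher-style ratio
`xi(C_k) = (C_k' Pi_IS C_k) / (C_k' Pi_ICS C_k)` — between-class over
within-class scatter projected on that axis — and reorders the basis by
non-increasing xi before truncation. Numerical conventions: the xi
denominator carries a ridge `1e-12 trace(Pi_ICS)/b`; ties are broken by
descending eigenvalue then original index, so the degenerate case
`Pi_IS = 0` reduces exactly to plain PCA; eigenvector signs are fixed by
making each vector's largest-magnitude entry positive; the cumulative
"contribution" used by the 90% dimension-selection rule is normalized xi
for the decreasing rule and normalized eigenvalues for plain PCA (explicit
dimensions 1-6 are also supported). The b x b (b = 10 features) primal
eigenproblem is used throughout — dimensions are tiny.

Both orderings span the same space; they differ only in which directions
survive truncation. The constructed fixture
`simulate_discriminant_classes()` makes the difference visible: class
separation and variance are anti-aligned across its four dimensions, so at
one retained component plain PCA keeps an almost uninformative
high-variance axis while the decreasing rule keeps a separating direction
(hold-out 1-NN accuracy ~53% versus ~80% on replicate draws).

## Association and evaluation

Association pools all subjects' windows (15 subjects x 7 windows = 105
paired observations by default) and computes matrix-form Pearson
correlations of the ten features with reference glucose, with two-sided
p-values from the exact t transform. Pooling windows across subjects and
states is a documented interpretation: published per-feature (r, p) pairs
in this design are only consistent with a pooled n of roughly 80-100, not
with n = 15. Z-scoring uses the population sigma.

Prediction is evaluated with nested leave-one-subject-out (LOSO)
cross-validation: the outer loop holds out each subject once; within a
training fold, features are z-scored with training statistics, the reducer
(DR-PCA or PCA) is fitted on training data only, and model hyperparameters
are chosen by an inner LOSO over the training subjects (KNN k in
{1,3,5,7,9}; random forest trees {100, 300}; RBF-SVM cost {0.1, 1, 10};
gradient-boosting depth {2, 3}). Pooled out-of-fold predictions yield RMSE
(mmol/L), MARD (%), Pearson r, and — for the state-classification task
that operationalizes "accuracy" — percent correct. A leakage canary in the
test suite verifies that corrupting held-out features changes no training
artifact. The predict-training-mean baseline is the no-information
reference every model must beat.

## Problem sizes and runtime

The statistical test-suite checks run the full study design (15 subjects,
21 channels, 10 + 60 min) at a 2 Hz analysis sampling rate, and the
acceptance script runs it at the full 10 Hz; the coupling, noise and
artifact conditions are identical in both. All replicated checks fix their
seeds. The whole default pipeline at 10 Hz completes in about a minute on
one CPU.

## Known limitations

* Step (baseline-shift) artifacts are attenuated, not removed; severe
  shift contamination will widen the channel t-test nulls.
* The synthetic linear glucose-HbO coupling cannot validate the
  physiological claim, only the pipeline's ability to recover such
  coupling when present.
* MARD is reported against reference values that themselves carry
  simulated meter noise; with noiseless references it would be slightly
  lower.
* The wavelet corrector assumes stationarity of the detail-coefficient
  distribution per level; long recordings with drifting artifact rates
  may violate this.
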