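---
title: "Predicting oxygen uptake from a forearm armband: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting oxygen uptake from a forearm armband: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Continuous oxygen uptake (VO2, mL·kg⁻¹·min⁻¹) is the standard measure of
the metabolic workload of physical labour, but measuring it directly
requires a portable metabolic analyzer that is impractical to wear on a
job site. `wearvo2` implements a pipeline that estimates second-by-second
VO2 from a single forearm armband providing 8-channel surface EMG
(200 Hz, signed 8-bit integers) and a 3-axis accelerometer and gyroscope
(50 Hz). The stages are: per-second statistical feature extraction,
correlation/mutual-information feature selection, min–max scaling,
recurrent-network regression (LSTM, BiLSTM or GRU), leave-one-subject-out
(LOSO) cross-validation, and task-level oxygen-cost reporting.

Because armband + analyzer recordings of this kind are not publicly
deposited, the package ships a synthetic cohort generator with a known
activity structure and a known feature→VO2 relationship, so that every
stage of the pipeline can be validated by parameter recovery.

## The synthetic generator

### Oxygen-uptake kinetics

A subject is described by resting uptake $v_r$, peak uptake $v_p$, and
on/off time constants $\tau_{on}, \tau_{off}$. A work bout of intensity
$i \in [0,1]$ drives VO2 toward the steady state
$v^\*(i) = v_r + i\,(v_p - v_r)$ by first-order kinetics. The 1 Hz series
uses the exact discretization of the first-order ODE,

$$v_{t+1} = v_t + \bigl(v^\*(i_t) - v_t\bigr)\,\bigl(1 - e^{-1/\tau}\bigr),$$

with $\tau = \tau_{on}$ when rising and $\tau_{off}$ when falling; it is
stable for any $\tau > 0$ and makes the step response exactly
$1 - e^{-t/\tau}$, which the tests exploit. Gaussian measurement noise
(default SD 1.0 mL/kg/min, a typical breath-by-breath noise level after
1 Hz smoothing) is added to the observed series; the noiseless trace is
kept as ground truth. Defaults $v_r = 5$, $v_p = 40$ mL/kg/min and
$\tau_{on} = 30$ s, $\tau_{off} = 45$ s are representative of active
young adults performing moderate-to-heavy work; off-kinetics are slower
than on-kinetics, as is physiologically typical.

### Motion and muscle activity

One accelerometer axis carries the 1 g gravity baseline that real
armbands show; each bout adds axis-wise phase-shifted sinusoids at the
bout's motion rate with amplitude proportional to intensity (0.5 g and
60 deg/s at full intensity), plus white noise. The EMG is
amplitude-modulated white noise quantized to the signed 8-bit range: the
per-sample envelope is

$$\text{gain} \times (0.2 + 0.8\,i) \times (1 + \text{load}/20\,\text{kg})
\times \text{channel gain},$$

a separable model in which motion intensity and handled load are
independently recoverable — the reason EMG distinguishes carrying a
light guardrail from a heavy baseboard when the motion looks the same.
The 0.2 baseline represents the minimum activation of an engaged muscle
and applies only while intensity or load is nonzero; at full rest only
the instrument noise floor remains, so a zero-noise rest bout is exactly
silent. Channel gains differ across the eight electrodes so channels are
not copies of each other.

All randomness flows from one master seed through per-stream derived
seeds, so cohorts are bit-reproducible. The 14-task scaffold script
template maps scaffold-building activities (walking, carrying frames,
jacks, crossbars, hammering, wrenching, baseboards, guardrails, ladder
climbs) to (intensity, load, motion-rate) combinations with loads from
0 to 17.2 kg. The field protocol rests each subject until heart-rate
recovery between five-minute bouts; rest duration is therefore exposed
as a free parameter (`rest_s`), defaulting to 60 s alongside the
desk-scale 120 s bouts used in the tests.

### What the generator does and does not emulate

It reproduces the sampling layout, value ranges, activity-bout structure,
first-order uptake kinetics, intensity/load coupling of the envelopes,
and inter-subject variability (jittered mass, rest/peak uptake and time
constants). It does not attempt physiologically faithful EMG spectra,
orientation/magnetometer channels, sensor drift, or motion artefacts.
Passing the recovery tests therefore shows that the pipeline extracts
and models the information the generator encodes — not that the trained
weights transfer to real recordings.

## Feature engineering

Each one-second window \[k, k+1) yields 17 statistics — sum, mean, min,
max, median, SD, coefficient of variation, variance, the
5/10/25/50/75/90/95th percentiles, skewness, excess kurtosis — for each
of 17 channels: the six IMU axes, the acceleration and gyroscope
resultants, the eight EMG channels, and EMGsum. Conventions, chosen once
so the brute-force oracle is unambiguous: population (biased) moments;
type-7 interpolated percentiles; zero-variance windows return
0 for SD, variance, CV, skewness and kurtosis; CV returns 0 when the
mean is exactly 0 (near-zero-mean gyro windows otherwise explode).
EMGsum is the per-sample sum of absolute channel values — a signed sum
of zero-mean 8-bit noise would cancel toward zero and carry no
amplitude information.

That yields 17 × 17 = 289 columns. The default `standard_290` mode appends
one lag feature, the previous second's EMGsum mean, for 290 columns; the
first row of each recording is dropped because the lag is undefined
there. The `extended_295` mode instead appends lag-1 and trailing
rolling-mean(3) columns for the per-second means of the acceleration
resultant, gyroscope resultant and EMGsum (295 columns; the rolling mean
uses partial windows at the start so the row count stays seconds − 1).
Both modes are first-class because the source feature taxonomy is
ambiguous about which derived columns existed; the published
selected-feature list (69 names such as `az_per50`, `res_gyro_max`,
`Acc_mean`, `EMGsum_lag1`) is producible under the union of the two
naming schemes, which the tests check at string level. A duplicated EMG
channel entry in that taxonomy is treated as a typo (8 channels +
EMGsum).

### Selection and scaling

A feature is kept iff |Pearson r| > 0.1 **and** mutual information
> 0.1 nats against the 1 Hz target. Mutual information uses the
Kraskov–Stögbauer–Grassberger k-nearest-neighbour estimator (k = 3) on
standardized marginals with a seeded 1e-10 tie-breaking jitter, making
it deterministic on quantized features. Because the estimator is
O(n²), rows beyond a cap (default 2000) are reduced by an evenly strided
deterministic subsample — an estimator setting documented here, not a
source of randomness. By default selection is fitted once on the full
corpus before cross-validation, replicating the original pipeline's
order of operations; a leakage-safe per-fold mode exists and reports
label which was used. The min–max scaler is always fitted on training
rows only; held-out values are deliberately not clipped, so
out-of-range test subjects are visible rather than silently saturated.

## The regressors

The three architectures share the stack: sequence input → two stacked
recurrent layers → dropout 0.3 → dense layer (ReLU) → dropout 0.3 →
linear scalar output (no activation on the regression head). LSTM cells
use gate order i, f, g, o with a single bias vector and forget-gate bias
1; GRU cells use r, z, n with the reset gate applied before the
candidate matmul; bidirectional layers run forward and backward passes
and concatenate them (the merge mode is not specified in the source
description; concatenation is the common default). A width-h
unidirectional layer on d inputs therefore has 4(dh + h² + h) parameters
for LSTM and 3(dh + h² + h) for GRU, which the tests verify against the
actual weight arrays.

Training is Adam (learning rate 0.001) on the MSE loss with a seeded
shuffle per epoch, early stopping after `patience` (default 10)
consecutive epochs without validation improvement, and restoration of
the best-validation weights — so the returned model's validation loss
dominates every later epoch. The validation split is the
chronologically last `val_fraction` of each subject's samples;
a chronological split avoids leakage through the lag feature. The
forward/backward passes are plain R matrix code; analytic gradients are
verified against numerical differentiation in the tests, which is the
main reason the implementation favours transparency over speed. Two
profiles exist: the full-scale profile (1024 recurrent and dense units)
matching the published architecture, and the desk-scale default
(32/32) used throughout the tests — training the 1024-unit model is not
required to validate any contract.

### Sequence length

The published pipeline reshapes the feature matrix to
\[samples, timestamps, features\] with one row per second; its sample
count equals its dataset's second count, implying one timestamp per
sample, and its lag/rolling features carry the short-range history. The
package default is therefore `seq_len = 1`. The sequence window is
nevertheless configurable, because with one timestamp a bidirectional
network degenerates toward its unidirectional twin, and because
oxygen-uptake kinetics (τ ≈ 30 s) extend far beyond the 1–3 s horizon
of the lag/rolling features: a memoryless map from per-second features
cannot represent the within-bout exponential transient at all. The
parameter-recovery experiment (below) uses 20-step windows — about
two-thirds of τ_on — which gives the bidirectional recurrence enough
context to reconstruct the kinetic state while leaving enough
non-overlapping windows per subject to train on. Windows never span
subjects, and the window's target is its last row's VO2.

## Evaluation

LOSO cross-validation trains on N−1 subjects and tests on the held-out
subject, N folds in all; reported metrics are unweighted means over
folds. `compute_metrics` returns MAE, MSE, RMSE (all mL/kg/min or its
square), MAPE (percent, excluding zero-target samples and reporting
their count — physiological VO2 is strictly positive, so exclusion is
explicit rather than consequential), Pearson r and R² = 1 − SSres/SStot.
The printed formulas for r and R² in the source material reduce to a
residual/total sum-of-squares ratio, which cannot equal a correlation;
the standard definitions are implemented (the published r/R² pairs are
consistent with them, e.g. 0.895² ≈ 0.80) and the literal ratio is
additionally reported as `eq5_literal` for transparency. The comparison
harness crosses {LSTM, BiLSTM, GRU} × {IMU+EMG, IMU, EMG} into nine
LOSO reports on one shared cohort.

## The parameter-recovery experiment

`parameter_recovery_experiment()` is the package's stand-in for a
human-subject validation: 6 subjects, the 14-task script at 120 s bouts
and 60 s rests (a desk-scale compression of the five-minute field
bouts), default noise, the desk-scale BiLSTM, and LOSO evaluation
against the noiseless ground truth, run for IMU+EMG and for EMG alone
on the same cohort and seed. Evaluation uses the work-bout seconds:
the field protocol records each activity as its own segment (its
dataset is almost entirely work time), so a faithful emulation does not
ask the model to predict the unobservable rest-decay transient from
featureless rest windows — though rest gaps still set the kinetic
carry-over into each bout. Sensor fusion is expected to beat EMG alone
because the synthetic VO2 target depends on intensity while the EMG
envelope confounds intensity with load; only the IMU disambiguates
them. Problem sizes here (6 subjects, ~1680 work seconds each, 120
training epochs) were chosen as the smallest cohort at which LOSO
recovery is stable.

## Numerical choices and degenerate inputs

* Percentile interpolation, population moments, zero-variance and
  zero-mean conventions: see above; all are asserted against independent
  oracles at 1e-9.
* Scaling maps constant columns to 0; selection assigns r = 0 to
  zero-variance features, which can therefore never be kept.
* Streams are validated on load: signed 8-bit EMG range (the first
  offending sample is named), strictly increasing timestamps, uniform
  sampling within 1 % jitter. Span trimming cuts to the intersection of
  the four streams and truncates to whole seconds so the one-second
  windows \[k, k+1) tile exactly; clock alignment beyond span trimming
  is assumed done upstream.
* Recordings shorter than 3 s are rejected (the rolling window is
  unsatisfiable); cohorts need at least 2 subjects (LOSO).
* Training aborts with a diagnostic on non-finite loss rather than
  returning NaN weights.
* A severity-band configuration for absolute oxygen cost (L/min) ships
  as a documented example only; published occupational thresholds are
  not reproduced as claims.

## Known limitations

* The from-scratch recurrent networks run on one CPU thread through
  BLAS; the full-scale 1024-unit profile trains slowly and is not
  exercised by the tests.
* The KSG estimator's subsample cap trades a little estimator variance
  for tractability on long recordings.
* The generator's EMG is spectrally white; methods that rely on EMG
  frequency content would need a richer simulator.
* Hyperparameter search is a deliberate reduced-grid utility (≤ 8
  candidates), not the full random search of the original protocol.
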