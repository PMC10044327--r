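---
title: "Estimating the ground reaction wrench from EMG and IMU signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the ground reaction wrench from EMG and IMU signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

A standing subject on a force plate exerts a six-channel *wrench* on the
ground: three forces (Fx, Fy, Fz) and three moments (Mx, My, Mz). Force
plates measure it directly but are expensive, stationary and rare outside
gait laboratories. `grfest` estimates the wrench from wearable sensors
instead: surface EMG of ten leg muscles (tibialis anterior, gastrocnemius
medialis, peroneus longus, rectus femoris and semitendinosus, both legs)
and up to four shank/thigh IMUs, using a recurrent network trained per
session against plate recordings.

Two motion classes are covered:

* **Posture control motion (PCM)** — continuous voluntary sway while
  standing, dominated by the ankle strategy: balance corrections are
  produced by ankle torque, so ankle-muscle EMG is highly informative.
* **Stepping motion (SM)** — discrete steps left, right or forward from
  quiet stance. Because EMG precedes force generation (the
  electromechanical delay), the estimated wrench carries *predictive*
  information about the step before the movement itself unfolds, which
  the direction decoder exploits.

Because no public recording of this kind exists, the package ships a
synthetic session generator with known ground truth. Every stage of the
pipeline is tested against that ground truth (parameter recovery), not
against the published human-subject error figures, which are not
reproducible without the original recordings. What *is* reproduced
exactly is the evaluation arithmetic: group mean ± SE aggregation,
accuracy, and inter-pattern deltas.

## The synthetic session generator

The generator is first-class, tested code; its defaults define the study
conditions used throughout the test suite.

**Centre-of-mass model.** Stance is an inverted pendulum about the
ankle. The anteroposterior tilt is quasi-periodic: a dominant component
at `sway_frequency_hz` (default 0.25 Hz), a weaker incommensurate
component at 2.2 times that frequency and a slow band-limited stochastic
drift; the mediolateral tilt is similar with 0.6 times the amplitude
(default amplitude 2.5 degrees, a typical voluntary-sway excursion). A
small vertical bob at twice the sway frequency gives Fz genuine,
IMU-predictable variation. Horizontal com acceleration follows the
small-angle pendulum relation `a = L * theta_ddot` with
`com_height_m = 1`.

**Stepping.** Step onsets are drawn near the mean `step_rate_hz`
(default 0.4 Hz) with timing jitter; each step carries a direction
(left / right / forward), a relative amplitude (SD 25%) and a duration
(0.8 s ± 20%). The kinetic transient is a biphasic lobe
(`sin(2*pi*u) * exp(-2.5*u)`): a directed shear push peaking near 20% of
body weight — the scale of a brisk step initiation, and comfortably
above the 5%-body-weight onset-detection threshold — followed by a
smaller rebound, with simultaneous vertical unloading/loading. The
mediolateral sign convention is +y = left: a leftward step produces a
positive Fy transient.

**Muscle drives.** Each of the ten muscles receives a smooth drive,
a softplus function of the com state *advanced* by the nominal
electromechanical lead `lead_time_s` (100 ms; per-step jitter ±50 ms).
TA/GAS form the anteroposterior antagonist pair, left/right PL the
mediolateral pair, RF/ST weaker thigh analogues. Stepping adds
direction-specific Gaussian bursts centred one lead time *before* each
onset. Smooth per-muscle noise (SD 0.04) makes channels informative but
not collinear; activations are clipped to [0, 1].

**Wrench assembly.** Newton–Euler about a single combined plate origin
(the two physical plates are collapsed; per-plate decomposition is out
of scope): `Fz = m*(g + az)`, `Fx = m*ax`, `Fy = m*ay`. Moments come
from centre-of-pressure excursions driven by *delayed* ankle-activation
differences — plantarflexor-minus-dorsiflexor for x (hence My),
left/right peroneal asymmetry for y (hence Mx) — plus per-step CoP
shifts; Mz is a small ankle-asymmetry term. This gives the moments an
EMG-borne component that IMUs alone cannot see, mirroring the empirical
finding that Mx degrades without EMG.

**Sensor models.** EMG channels are unit-RMS Gaussian carriers
band-limited to 20–450 Hz, amplitude-modulated by the upsampled
activation, plus white baseline noise (SD 0.05 relative to the carrier)
and a sub-20 Hz motion-artifact drift (relative amplitude 0.3) — so all
informative content lies in the band the band-pass keeps, and the
artifact is exactly what the band-pass removes. IMU accelerometers see
the gravity projection under segment tilt plus the segment's share of
com acceleration; gyros see segment angular velocity; shank sensors
(1, 4) use smaller segment gains than thigh sensors (7, 9), because
under the ankle strategy the segments above the knee move more. Plate
noise is white at 5% of each channel's own SD. Noise defaults were
chosen so that the trained model's test percent RMSE lands in the
5–20% band, the regime of the published tables (see "What the
benchmark shows" below).

**Rates and determinism.** EMG is synthesized at 1111.11 Hz, IMU and
wrench at 148.148 Hz (the plate rate is not independently specified;
sharing the IMU timebase keeps every decimation factor an exact
integer). Each generation stage draws from its own deterministic
sub-seed of `seed`, so every public operation is bit-reproducible both
standalone and inside `generate_session()`.

## Signal processing

The chain reproduces the standard EMG/kinetics preprocessing:

1. **EMG band-pass** — 4th-order Butterworth, 20–450 Hz: below 20 Hz
   lies motion artifact and motor-unit firing noise; above ~450 Hz there
   is no muscle-contraction content.
2. **Linear envelope** — full-wave rectification followed by a 3 Hz
   4th-order Butterworth low-pass. Rectification is not stated in the
   source description of the envelope; rectify-then-low-pass is the
   standard linear-envelope construction and is documented here as this
   package's convention.
3. **Auxiliary low-pass** — the same 3 Hz filter applied to IMU and
   wrench channels.
4. **Decimation** — every 15th EMG sample and every 2nd IMU/wrench
   sample, landing exactly on the common 74.074 Hz feature timebase
   (1111.11 / 15 = 148.148 / 2 = 74.074). The 3 Hz low-pass is the
   anti-aliasing stage, so plain sample picking is exact; polyphase
   resampling would add nothing for integer ratios.

All offline filtering is zero-phase (forward–backward), because
EMG-to-force *timing* carries the predictive information and causal
filtering would delay each stream differently. Numerically, each pass
seeds the direct-form-I state at the constant-input equilibrium of the
first padded sample and uses odd-reflection padding of three filter
lengths at both ends; this keeps DC exact to ~1e-9 even for the very low
relative cutoff (3 Hz at 1111.11 Hz) where naive zero-initialized
filtering has metre-scale start-up transients. A `zero_phase = FALSE`
flag provides the causal single-pass variant for streaming-style use; it
is not the tested default.

## Dataset construction

`input_patterns()` enumerates the six sensor combinations: all-EMG (d =
10), four IMUs (24), both (34), below-knee EMG (6), shank IMUs (12) and
below-knee EMG + shank IMUs (18). The feature frame is split
**chronologically** 50/50 — random splitting of overlapping time windows
would leak temporal context across the train/test boundary — with the
floor on the training side for odd lengths. Inputs are z-scored with
training-half statistics only; targets stay in physical units in the
dataset contract.

Training uses non-overlapping contiguous windows (default 128 frames,
about 1.7 s — several electromechanical delays long, and short enough to
give a usable number of truncated-BPTT windows from a 60 s training
half) with the hidden state reset at window boundaries; the trailing
partial window is kept.

## The LSTM regressor

The cell is implemented directly from its gate equations with gate order
forget / generation / input / output:

    f_t = sigma(x_t Wxf + h_{t-1} Whf + bf)
    g_t = phi  (x_t Wxg + h_{t-1} Whg + bg)
    i_t = sigma(x_t Wxi + h_{t-1} Whi + bi)
    o_t = sigma(x_t Wxo + h_{t-1} Who + bo)
    c_t = f_t . c_{t-1} + g_t . i_t
    h_t = o_t . tanh(c_t)

The generation-gate nonlinearity `phi` is the **sigmoid by default** —
the form the source equations are printed with — although the
conventional LSTM uses tanh there. A sigmoid generation gate constrains
`g_t . i_t` to be positive, so the cell state can only grow toward
positive values between forget events; whether the printed form is
intentional cannot be resolved from the text, so both behaviours are
implemented (`g_gate = "sigmoid"` / `"tanh"`), both are
oracle- and gradient-tested, and neither is asserted as "correct". The
benchmark results in this package use the printed sigmoid form.

A per-frame affine head (H × 6) maps the hidden state to the wrench —
the minimal seq-to-seq reading of a "unit time step": one output frame
per input frame. Inverted dropout (p = 0.5) acts on the hidden state
before the head in training mode only.

**Training.** Single layer, H = 64 hidden units, batch size 64 windows,
Adam with learning rate 0.001, MSE over all six channels equally
weighted — the study configuration. Two choices the study leaves open
are made here and matter in practice:

* **Target scaling.** Targets are z-scored internally for optimization
  and predictions are mapped back to physical units. With raw targets
  (Fz ≈ 686 N) and Adam at lr = 0.001, reaching even the output bias
  would take ~7 × 10^5 updates — far beyond any plausible epoch budget —
  and the loss would be dominated by Fz alone. Standardization also
  realises "all six channels equally weighted" literally.
* **Epoch budget.** Max 400 epochs with early stopping (patience 25) on
  the last 20% of the training half; the best-validation parameters are
  kept. On the benchmark sizes (~3,500 core training frames, 28 windows,
  one Adam step per epoch batch) convergence is still improving at 200
  epochs and typically saturates by 300–400 within ~1.5 min of CPU.

Weights initialize uniform in ±1/sqrt(H) with the forget-gate bias at
+1 (long-memory ease); initialization, batch order and dropout masks all
derive from the training seed, so a fixed seed reproduces the loss
trajectory exactly. Non-finite loss aborts with a diagnostic rather than
silently continuing.

**Verification.** The forward pass matches an independently written
per-equation oracle (explicit per-gate slices, plain loops) to 1e-10 on
100 random small instances, for both generation-gate modes; analytic
BPTT gradients match central finite differences to 1e-4 relative on tiny
instances. These two checks pin the implementation to the equations
rather than to its own behaviour.

## Evaluation

`percent_rmse()` normalizes the RMSE by the **measured channel's range**
(max − min) on the evaluation segment. The published tables report
"%RMSE" without defining the denominator (their column headers even
retain [N] / [Nm] units); range normalization is the common NRMSE
convention for signals oscillating about varying baselines, and the
denominator is exposed (`range | peak | std`) so other conventions can
be matched. The consequence worth knowing: SM percentages come out
*smaller* than PCM ones here, because step transients make the range
denominator large — the published study found the opposite ordering, but
with an unknown denominator and real recordings the orderings are not
comparable.

Group aggregation uses the sample (n−1) standard deviation over the
three axes divided by sqrt(3); this convention reproduces the published
"Average ± SE" columns from their per-axis values exactly — all 24
averages and 22 of the 24 SE cells — which resolves the n vs n−1
ambiguity. The two remaining published SE cells (both in the
stepping-motion moment group) are inconsistent with their own printed
per-axis values under any standard convention and are pinned down as
published typos in the test suite rather than papered over with a loose
tolerance. Accuracy is `100 − mean GRF %RMSE`, and
`compare_patterns()` gives the signed inter-pattern deltas (e.g. the Mx
gap between shank-IMU-only and EMG+IMU configurations). Display rounding
(3 significant figures per axis, 2 decimals for averages) never feeds
back into computation.

## Direction decoding

The source work states only that "simple support vector machine
decoding" predicts motion direction from the estimated GRF in the early
phase of an action; every concrete choice below is this package's
minimal faithful reading, all exposed in configuration:

* **Onsets** — `sqrt(Fx^2 + Fy^2)` crossing 5% of body weight after at
  least 500 ms below it, 1 s refractory. Body weight defaults to the
  median Fz of the stream itself, so the detector needs no external
  calibration.
* **Features** — means and slopes of Fx, Fy, Fz over the early and late
  halves of a 200 ms post-onset window, onset-anchored (12 values).
* **Classifier** — linear one-vs-rest SVMs (largest signed margin wins)
  on standardized features.

Decoding always operates on the *estimated* wrench; measured GRF is used
only as an upper-bound comparison, never as a decoding input. The
benchmark bar (≥ 80% held-out accuracy at default noise, with label
permutation collapsing to the binomial chance band) is an internal
synthetic-data standard, not a published claim — the source reports no
quantitative decoding accuracy.

## What the benchmark shows — and what it does not

The acceptance benchmark (120 s sessions, pattern 6, H = 64, ~4,400
training frames; runtimes of a few minutes on one CPU) demonstrates
*parameter recovery*: the generator's activation-to-wrench mapping is
deterministic given the configuration, so a correctly implemented
pipeline must approach the noise floor, and the trained model must beat
the mean predictor on every channel and land force-axis %RMSE under
20% (PCM) / 25% (SM). Typical PCM GRF means land near 10–12%, inside
the 5–20% regime of the published tables.

Passing these tests shows the pipeline is internally correct and the
estimation problem it solves is realistic in structure. It does **not**
show that the published human-subject error levels are reproduced: the
synthetic data has no crosstalk between muscles, no electrode lift-off
or impedance drift, no soft-tissue artifact on the IMUs, no
subject-to-subject anatomical variation, and a com-driven activation
model far simpler than real motor control. Hill-type muscle dynamics,
subject-specific anthropometry and per-plate wrench decomposition are
explicit non-goals.

## Degenerate inputs and numerical edge cases

* Zero sway amplitude with zero activation noise gives constant baseline
  activations, a constant wrench and a statics-only IMU — useful for
  calibration-style tests.
* A constant measured channel makes percent RMSE undefined; it errors
  rather than returning Inf.
* Zero-variance feature channels standardize to zero with scale 1 and a
  warning.
* An all-quiet stream yields zero step onsets; a zero detection
  threshold is rejected as degenerate.
* Signals shorter than the filter padding (3 filter lengths + 1) are
  rejected with an explicit length message.
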