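---
title: "Methods: phase-based swimming performance evaluation from a sacrum IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-based swimming performance evaluation from a sacrum IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and numerical choices behind
`swimphase`, in the spirit of a statistical-methods appendix: what is
computed, under which assumptions, and where the genuinely open design
decisions were settled.

## Frames and axis conventions

Three frames are used. The **sensor** frame is the device's own axes. The
**anatomical** frame is body-fixed: `x` mediolateral, `y` longitudinal
(cranial positive), `z` anterior–posterior. The **global** frame is
pool-fixed: `X` lateral, `Y` the swimming direction, `Z` vertical up,
right-handed. Accelerometers report specific force, so a static sensor reads
+9.81 m/s² along the global `Z` once rotated.

The field's axis vocabulary is not used consistently across instruments and
authors; we fix the assignment by requiring internal consistency with the
Euler-angle formulas below. With `q = (q1, q2, q3, q4)` (scalar first)
mapping anatomical vectors into the global frame via
`v_G = q ⊗ [0, v_A] ⊗ q*`, the angles are

```
psi   = atan2(2 q2 q3 − 2 q1 q4, 2 q1² + 2 q2² − 1)
theta = −asin(2 q2 q4 + 2 q1 q3)
phi   = atan2(2 q3 q4 − 2 q1 q2, 2 q1² + 2 q4² − 1)
```

These are exactly the ZYX angles of the *transpose* of the body-to-global
rotation, i.e. `Rᵀ = Rz(psi) Ry(theta) Rx(phi)`. That identification forces
`theta` to be the angle about the body `y` axis, `phi` about `x` and `psi`
about `z`; naming `theta` roll-about-longitudinal, `phi`
pitch-about-mediolateral and `psi` yaw-about-anterior–posterior is therefore
only coherent if mediolateral = `x` and anterior–posterior = `z`, which is
the convention adopted everywhere in the package. The alternative labelling
(mediolateral = `z`) would place prone swimming exactly at the
`theta = ±90°` gimbal singularity of these formulas, where `phi` and `psi`
are not separable — a strong internal argument for the chosen assignment.
One consequence, documented on `quaternion_to_euler()`, is that a body
rotation of `+a` about the longitudinal axis reads `theta = −a`; the sign
convention is fixed once by exact round-trip consistency with
`euler_to_quaternion()` (`q = conj(qz(psi) ⊗ qy(theta) ⊗ qx(phi))`), which
unit tests verify to 1e−9 away from the singularity. The `asin` argument is
clamped to [−1, 1] with a warning at the singularity itself.

Euler traces are unwrapped along time before statistics are taken: prone
postures sit near `phi ≈ ±180°`, where raw `atan2` output alternates sign
sample to sample and would corrupt `Mean`/`Range`/`SD`.

## Orientation estimation

**Initial orientation.** The swimmer floats upright for about five seconds
before the lap. The mean accelerometer direction over that window is mapped
to the global vertical by the *smallest* rotation; yaw about the vertical is
zero by definition, because a magnetometer is not available under water and
the pool's swimming direction, not magnetic north, is the meaningful
heading. A gyroscope-RMS check (default 0.2 rad/s) warns if the window was
not static.

**Fusion.** Orientation is propagated by gyroscope integration
(`q̇ = ½ q ⊗ [0, ω]`) and corrected each sample by a normalized
gradient-descent step on the objective aligning the quaternion's predicted
gravity direction (the third row of `R(q)`) with the normalized
accelerometer vector — the standard IMU-only complementary filter of this
family, at 500 Hz with explicit Euler integration and renormalization each
step (unit norm holds to 1e−9 by construction). The gain `beta` (default
0.1 s⁻¹) sets the correction authority: the normalized step corrects
orientation error at ≈ `2·beta` rad/s, so a 15° initialization error is
absorbed in well under two seconds, while gyro noise (0.01 rad/s white)
contributes only milliradians of drift over a 20 s lap.

The accelerometer only measures gravity when the body is unaccelerated, so
the correction is **gated**: samples whose specific-force norm deviates from
9.81 m/s² by more than `acc_gate = 2` m/s² (the push-off, strong propulsion
transients) propagate by gyroscope alone. Gating cannot detect accelerations
*perpendicular* to gravity of near-gravity norm: during the glide the
sustained ~0.5 m/s² drag deceleration is absorbed into a tilt error of a few
degrees, a structural ambiguity of accelerometer-corrected filters rather
than an implementation artifact. Its main downstream effect is a bias on
IMU-integrated velocity (see DPS below); phase-level statistics inherit only
a small, across-laps systematic shift that a regression model absorbs.

**Yaw anchoring.** The initial-orientation step cannot know which way the
swimmer faces, so after rotation to the global frame the pipeline checks the
sign of the integrated forward acceleration over the push-off burst and, if
negative, rotates the frame 180° about `Z`. The swimming direction defines
`+Y` by construction.

## Phase segmentation and cycle separation

The detector is a documented heuristic (the full camera-validated detector
of the companion protocol is not reproducible from published material);
camera-style annotations can be supplied instead and pass through verbatim,
mirroring the dual camera/IMU analysis path.

* **Lap bounds.** Lap start: forward acceleration (low-passed at 5 Hz so
  push vibration does not fragment the burst) exceeds `theta_push`
  (1.5 m/s²) for ≥ 50 ms. Lap end: last sample of sustained activity
  (gyroscope magnitude > 0.8 rad/s or |AccY| > 2.5 m/s²), with quiet gaps up
  to 2.5 s (the glide) bridged. A second activity region triggers a warning
  and the first lap is returned.
* **Push → Glid.** Smoothed forward acceleration drops below `theta_push`
  (sustained 30 ms).
* **Glid → StPr.** Kick onset: the 1–4 Hz band power (200 ms moving RMS) of
  the mediolateral gyroscope exceeds `max(5 × baseline, 0.3 rad/s)`, the
  baseline being the median envelope inside the quiet glide (0.4–0.9 s after
  the push ends, after the pitch-over from upright to horizontal has
  settled).
* **StPr → Swim.** First prominent peak of the low-passed (1.5 Hz) cycle
  channel, sign-agnostic because the prone pose maps the body axis onto the
  negative global axis for some techniques. If the first stroke peak
  coincides with the kick onset, StPr collapses to a minimum width (0.1 s)
  with a warning.
* **Cycles.** Positive peaks of the anatomical longitudinal angular velocity
  (front crawl, backstroke) or mediolateral angular velocity (breaststroke,
  butterfly), low-passed at 2.5 Hz, peak height ≥ 30% of the channel
  maximum, and a minimum separation of half the median inter-peak interval.

Phase intervals are half-open `[on, off)` so that sample membership and
durations are unambiguous at 500 Hz; integrals, by contrast, cover the
closed interval so the full duration is integrated.

## Micro-variables

The lap-level catalogue has 126 named columns, `<Phase>.<Func>(<Signal>)`,
spanning four categories (propulsion, posture, efficiency, duration/rate);
per-cycle rows carry a 31-column analogue plus cycle duration and DPS. Two
definitions were genuinely open and are settled as follows:

* **`Momentum` vs `Int`.** `Int` is the net trapezoidal integral of the
  forward acceleration (net velocity change). `Momentum` is interpreted as
  the mass-normalized *propulsive impulse*: the integral of the positive
  part only. This makes the two distinct whenever braking occurs and ties
  `Momentum` to propulsion specifically.
* **Efficiency ratios.** `Eff` and `Eff_dir` are ratios of *time integrals*
  (positive forward acceleration over negative forward acceleration, and
  over the acceleration norm), not sample counts: integrals are invariant to
  the sampling rate. A zero denominator flags the value undefined; by
  default an observation containing an undefined variable is dropped with a
  logged reason, since a partially-missing row cannot enter the selection
  stage.

Angles enter the feature table in degrees, accelerations in m/s², angular
velocities in rad/s, rates in min⁻¹, durations in seconds.

**Distance per stroke.** DPS needs a forward-velocity estimate. The default
is IMU-only: integrate the global forward acceleration from the lap start
(zero velocity at the wall) to anchor the Swim-phase velocity, integrate
across Swim, and remove drift linearly so the net velocity change over the
phase is zero (the steady-state constraint). Double-integration drift is the
known failure mode of sacrum IMUs, and the glide tilt ambiguity above leaks
into the anchor, so the IMU-derived DPS is a relative, not absolute,
measure; when a corrected reference trace is available it can be passed to
`extract_micro_variables(velocity = ...)` for an absolutely-scaled DPS. Both
paths are exercised in tests; the 5%-accuracy check runs on the
reference-velocity path.

## Goal metrics

The tethered speedometer sits `h = 0.62 m` above the water line, so cable
velocity over-reads the forward velocity near the wall. With `d0` the
initial horizontal distance from the anchor, the cable length is
`L(t) = sqrt(d0² + h²) + d_cable(t)`, the horizontal position
`x = sqrt(L² − h²)`, and `v_f = v_cable · L / x` (`= v_cable / cos α`); the
displacement is re-based to zero at the start. The correction factor is
1.0077 at 5 m and decays monotonically to 1. The exact projection model used
by the original instrument is unpublished; this right-triangle model is the
standard reading.

The eight metrics follow directly: maximum velocity in Push (global maximum;
the push profile is single-peaked), velocity at Glid end (linear
interpolation), time-average velocity over StPr, over each cycle, and over
Swim (trapezoidal mean), first crossings of 5 m and 15 m from the wall
(linear interpolation between samples, so halving the 100 Hz rate moves them
by less than one sample period), and pool length over lap duration. A
`sync_offset` parameter aligns the trace clock with the annotation clock,
since cross-instrument synchronization error is a recognized limitation of
the protocol.

## The association model

Per goal metric, candidate variables are restricted to the relevant phases:
Push for the push maximum velocity, Glid for the glide end velocity, StPr
for its average velocity, Swim for the phase average, per-cycle variables
for the per-cycle average, Push+Glid for T5m, Push+Glid+StPr for T15m and
all phases for the lap average velocity.

Columns are z-scored with the *sample* standard deviation (constant columns
dropped with a warning). Multicollinearity is removed by iterating: compute
`VIF_j = 1/(1 − R²_j)` for each column regressed on the others, remove the
largest until all are below the threshold (default 10 — the usual rule of
thumb; the protocol literature gives none). Ties break by column order,
making the filter deterministic.

LASSO selection uses an explicit 100-value log-spaced penalty grid (down to
1e−6 of the largest useful penalty; an explicit grid also avoids the
optimizer's early path termination on near-perfect fits) with the penalty
chosen by 10-fold cross-validation under the one-standard-error rule — the
parsimonious standard for *selection*. Relative weights are
`100·|β_j|/Σ|β|`; coefficients below 1e−10 count as zero; weights sum to
100 by construction. Variables under the 5% cutoff are neglected. Category
contributions are the sums of selected members' weights, reported both raw
and renormalized to 100% (whether the original analysis renormalized after
the cut is unstated, so both are emitted). If the chosen penalty zeroes
everything (a null response), the largest penalty retaining one coefficient
is used, with a warning.

Prediction quality is evaluated by leave-one-out cross-validation on the
selected variables: each observation is predicted by a LASSO refit on the
others, with the penalty re-chosen by 10-fold CV *inside* every fold
("nested") to avoid optimistic bias — for the per-cycle target (hundreds of
observations) a fixed full-data penalty is reused across folds as a
computational compromise, and single-predictor designs fall back to
ordinary least squares since a one-column LASSO is not defined in the
fitting library. `R²` is computed on the pooled held-out predictions
(`1 − SSE/SST`; per-fold averaging is the other unstated possibility),
`RMSE` on the same residuals, and the relative RMSE as a percentage of the
response mean (undefined, with a warning, for a centred response).

## The synthetic-lap generator

The generator is the package's ground truth and defines the study
conditions: 500 Hz six-axis IMU, 100 Hz speedometer, 25 m pool, a 5 s upright
float before the push-off, four techniques, paces 0.7–1.0.

Forward velocity is piecewise: a quarter-sine rise to `v_peak` over the
0.3 s push with a band-limited leg-drive vibration (5 m/s² at 10 Hz,
windowed to vanish at the push boundaries so the glide entry velocity is
exactly `v_peak` — the vibration also gives the push phase the negative
acceleration excursions that real push-offs show, without which `Eff` would
be undefined there); exponential glide decay `v_peak·e^(−kt)` with
`k = 0.4 s⁻¹`; a smoothstep recovery to `v_swim` with a kick-rate ripple
during StPr; and `v_swim(1 + m·sin(2π f t))` during Swim, ending when the
integrated displacement reaches the pool length, followed by a fast decay
(the wall touch). Technique defaults (full pace): `v_swim` 1.60/1.15/1.45/
1.40 m/s, stroke rates 0.80/0.60/0.65/0.75 Hz and intra-cycle modulation
0.08/0.35/0.25/0.08 for front crawl, breaststroke, butterfly and
backstroke — values in the range reported for elite 25 m trials, with
breaststroke carrying the large intra-cycle velocity variation
characteristic of the technique.

Orientation starts upright, slerps to the swimming pose (prone, or supine
for backstroke, plus a small pelvis incline) during the push, and oscillates
about the technique's cycle axis (roll for alternating-arm strokes, pitch
for simultaneous strokes) during Swim, with 3 Hz mediolateral kicks during
StPr. Body angular velocity is derived from the quaternion sequence by
central differences, and the accelerometer signal is the true global
acceleration plus gravity rotated into the body frame, then mapped to the
sensor frame through a mounting rotation and biases that the calibration
object undoes. White Gaussian noise is added (0.05 m/s² accelerometer,
0.01 rad/s gyroscope, 0.005 m/s reference velocity — the reference device
is an encoder-based instrument whose filtered output is far cleaner than
the IMU).

The cohort generator draws a latent ability per swimmer
(`alpha ~ N(0, 1)`) that consistently modulates swimming velocity (±6%/SD),
push strength, glide drag, stroke and kick rates and posture (better
swimmers glide flatter), with ~1.5% per-trial jitter; each swimmer performs
the four progressive paces per technique, reproducing the 76-lap-per-
technique sample structure. All randomness flows through one integer seed;
identical seeds reproduce every output bit for bit.

**What the generator does not emulate** — and what passing tests therefore
do not establish about real data: hydrodynamic force generation (velocity
profiles are prescribed, not simulated), soft-tissue artefact, sensor bias
drift and temperature effects, breathing asymmetry, inter-arm coordination
variability, turns and dive starts, and annotation error in the reference
systems. Results on synthetic cohorts demonstrate the pipeline's internal
correctness and statistical calibration, not field validity.

## Problem sizes and numerical tolerances used in the tests

The test-suite sizes are the package's own choices for a thorough desk
check: 1,000 random quaternion/vector pairs against the rotation-matrix
oracle (1e−10), 10,000 Euler round-trips (1e−9), 50 simulated laps across
the four techniques for segmentation recovery (0.2 s boundaries, ±1 cycle),
a 19-swimmer × 4-pace cohort (76 laps) for the end-to-end model check, and
50-seed Monte-Carlo runs for the selection and LOO-CV calibration
properties (planted 5-of-30 support at n = 76; theoretical R² = 0.85 with
noise SD chosen by the variance decomposition `R² = Σβ²/(Σβ² + σ²)`).

## Known limitations

* The phase detector is a documented stand-in for the camera-validated
  detector of the companion protocol; exact agreement cannot be asserted.
* IMU-only velocity (hence DPS) is relative: the glide tilt ambiguity
  biases the anchor by design of the sensing modality.
* The linear LASSO model family is intentionally restrictive; non-linear
  estimators are out of scope.
* Goal-metric extraction assumes one-way laps starting with an in-water wall
  push-off; turns and dive starts are not handled.
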