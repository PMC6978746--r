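---
title: "From muscle force to gesture: the armsense pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From muscle force to gesture: the armsense pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armsense)
```

## The measurement model

`armsense` models a forearm armband that senses muscle contraction
mechanically. Three force-sensitive resistors (FSRs) press on flexor carpi
ulnaris (channel 1), flexor carpi radialis (channel 2) and extensor
digitorum (channel 3). A contraction swells the muscle, increases the
normal force on the sensor, and — through a current-mirror conditioning
circuit — produces an output voltage approximately linear in force:

$$ V = R_G \, V_{CC} \, (g_0 + s\,F), $$

where $g_0$ is the rest conductance, $s$ the conductance sensitivity
(S/kg) and $F$ the applied force. `transduce()` implements this map with
clamping at the supply rail and 12-bit quantization over $[0, V_{CC}]$;
`inverse_calibrate()` inverts it below saturation with a worst-case error
of one ADC step divided by the volts-per-kg slope. No calibration constants
are published for the sensors, so the defaults fix conventions only: a
common 2 V/kg slope (so a ~1 kg contraction sits mid-range of the 5 V ADC
span), a 0.5 V zero-force baseline, and sensitivities inversely
proportional to the per-channel gain resistors (850, 790, 960 Ω) so the
three channels share one gain, as the hardware intends.

Because each gesture produces a characteristic force distribution over the
three muscles, the vector of per-channel forces separates eight postures:
rest, wrist flexion/extension/adduction/abduction, wrist rotation
(supination), finger abduction, and clenched fist, coded 0–7 in that
protocol order.

## What the synthetic generator emulates

Subject recordings for this kind of device are not publicly distributed,
so the package ships a first-class generator
(`default_activation_profile()`, `generate_trial()`,
`generate_session()`). A calibration session is eight recording blocks, one
per gesture class, of ten repetitions each: a trapezoidal contraction burst
(linear rise, held plateau, linear fall) followed by a rest gap, over a
0.1 kg armband-fastening preload, sampled at 1 kHz.

The per-channel force during gesture $g$, repetition $r$, is

$$ F_c(t) = \text{preload} + o_c + a_c \, j_{rc} \, e(t)\, P_{cg} +
\varepsilon_t, \qquad \varepsilon_t \sim \mathcal N(0, \sigma^2), $$

clamped at zero (an FSR cannot report negative force), with

* $P$ — a 3×8 plateau matrix (kg) encoding the functional anatomy: the
  flexors dominate wrist flexion (with ulnaris alone for adduction and
  radialis alone for abduction) and extensor digitorum dominates wrist
  extension and finger abduction; the clenched fist activates everything.
  Pairwise column distances exceed six noise SDs, which is what makes the
  default cohort "well separated": gesture clusters in feature space do
  not overlap, as observed on real recordings.
* $e(t)$ — the trapezoidal envelope. Holds last 2 s ("a couple of
  seconds"); transitions are brisk (0.1 s). The transition speed is not a
  free cosmetic choice: the 40% threshold keeps the upper 60% of each ramp
  inside the segment, so the ramp-to-hold ratio directly sets the deviation
  between a segment's mean and its median. At 0.1 s rise the deviation is
  ≈1.8%, consistent with the <2% observed on real held postures; at 0.5 s
  it would exceed 7%, which no real recording shows.
* $j_{rc} \sim \text{Lognormal}(0, 0.05)$ — per-repetition amplitude
  jitter: a subject does not reproduce a contraction force exactly across
  repetitions. Without it repetitions collapse to numerically identical
  feature points and pooling subjects costs nothing, which contradicts how
  such devices behave across users.
* $a_c \sim \text{Lognormal}(0, 0.25)$, $o_c \sim U(-0.05, 0.05)$ kg —
  per-subject channel gain and offset, fixed per subject
  (`draw_subject_profile()`), modelling anatomy and armband placement.
  Re-donning the armband is modelled as a fresh draw composed onto the
  subject's own.
* $\sigma$ — sensor noise, default 0.02 kg (2% of the largest plateau).

What the generator does **not** emulate: force drift and fatigue within a
session, FSR hysteresis and temperature drift, motion artifacts, transition
co-contractions between postures, and realistic magnitudes of cross-subject
disparity. Consequently, passing tests show that the pipeline is correct
and well-behaved under the stated statistical structure — per-subject
accuracies near 100% on the default cohort say nothing about accuracy on
real muscles, and the pooled-database degradation reproduces the *ordering*
seen in practice (pooled < per-subject) but not its dramatic magnitude.

## Preprocessing and segmentation

`preprocess()` subtracts, per channel, the minimum observed over a rest
reference (the fastening-pressure offset) and normalizes all channels
jointly by the global maximum absolute value, so a session peaks at exactly
1; `preprocess_session()` applies one shared transform to all blocks so
features are comparable across gesture classes.

`segment_recording()` selects the channel with the largest peak-to-peak
amplitude (ties to the lowest index) and thresholds it at

$$ T = \min x + 0.40\,(\max x - \min x), $$

i.e. 40% of the maximum variation, applied relative to the signal minimum —
this makes segmentation invariant under positive affine transforms of the
channel, so it is indifferent to whether normalization happens first.
Segments are maximal runs at or above $T$, after merging runs separated by
less than `merge_gap` (0.1 s) and dropping runs shorter than
`min_segment_duration` (0.5 s); the two guards reject noise spikes and
plateau dips that the bare threshold rule would mishandle, and a flat
signal yields an empty result rather than an error. Ground-truth labels,
when a timeline is available, are assigned by maximal overlap.

Rest produces no threshold crossing, so rest repetitions are represented by
fixed-length windows tiled across the rest block (or placed in
between-segment gaps); their length defaults to the median detected gesture
segment duration, so rest rows have the same sample support as gesture
rows at any protocol timescale.

One deliberate deviation from a single-channel design: for a *randomized*
mixed-gesture sequence (the second-session reproducibility protocol), no
single channel's threshold can recover gestures that barely activate that
channel. Since that session is guided — the prescribed sequence is known —
`timeline_database()` windows it from the ground-truth timeline instead.

## Features and databases

Per segment, the mean and sample (n−1) standard deviation of each channel
give six features plus the label (`extract_features()`); a full session
yields the 80-row database (10 repetitions × 8 gestures).
`median_check()` reports the percent deviation between segment mean and
median — small under the symmetric-noise model, which is why the cheaper
mean is the feature and the median is not. `project_sensors()` restricts to
sensor pairs (4 features) or singles (2 features) for the ablation study;
`combine_databases()` concatenates subjects with provenance.

## Classifiers

All four classifiers are self-contained implementations with a common
`predict()` interface, serializable to JSON:

* **LDA** — closed form: class means, pooled within-class covariance
  (divisor $n-K$), priors from class frequencies, linear discriminant
  scores; the covariance is ridge-regularized by $\epsilon\,\mathrm{tr}
  (\Sigma)/d$ on the diagonal when ill-conditioned.
* **QDA** — per-class covariances with the same regularization.
* **Linear SVM** — one-vs-one soft-margin hyperplanes ($C = 1$, the usual
  multiclass SMO toolchain default), each solved by sequential minimal
  optimization of the dual with maximal-violating-pair working-set
  selection and a $10^{-6}$ KKT gap; prediction by majority vote with ties
  broken by summed decision values. Pairwise objectives agree with an
  independent QP solution to well under 0.1%.
* **k-NN** — stored instances, Euclidean metric, $k = 1$, vote ties to the
  lowest gesture code.

Polynomial/RBF kernels, random forests and neural networks are out of
scope: no architecture or kernel parameters are specified for them, and
the evaluation harness accepts any trainer closure, which is the extension
point.

## Evaluation protocols

`cross_validate()` implements stratified k-fold (default 10, fold shuffle
seeded, per-class cyclic assignment; falls back to unstratified with a
warning when a class has fewer rows than folds) and leave-one-out, which is
deterministic. The headline accuracy is the mean of per-fold accuracies —
the convention of averaging the ten fold accuracies — with the pooled
accuracy over held-out predictions also reported; with equal fold sizes the
two coincide. Confusion matrices accumulate held-out predictions, rows =
true gestures. `ablation_study()` evaluates all seven sensor subsets;
`reproducibility_eval()` classifies a later session with an earlier model,
no retraining. `run_cohort_experiment()` drives the whole design over a
synthetic cohort and writes the study-shaped tables.

## Real-time decoding

`calibration_session()` runs the batch pipeline on a protocol session and
bundles the trained model with the session's preprocessing transform.
`stream_decode()` then consumes samples in order and, every 100 ms
(non-overlapping windows; the 10 Hz output rate forces stride = window),
computes per-channel mean/SD, classifies, and emits a decision carrying the
gesture's one-byte code (0–7; 8–255 reserved). A finite source yields
exactly `floor(duration × rate)` decisions; a trailing partial window is
dropped. Windows straddling a rise or fall are classified as-is — there is
no transition state — which is the known mislabel source during posture
changes; `majority_per_plateau()` therefore also reports the per-attempt
view (majority decision inside each held plateau) alongside the per-window
view.

Because the plateau signal is stationary, a 100 ms window's mean matches
the segment-level mean; its SD is smaller than a segment's SD (which
includes the ramp shoulders), but class separation is dominated by the mean
coordinates, so windowed decisions during a held posture match the batch
label.

## Numerical choices and degenerate inputs

* Half-open, 0-based `[start, end)` sample intervals everywhere.
* Segment SDs use the sample (n−1) convention; segments are hundreds of
  samples, so this is immaterial but fixed for reproducibility.
* All randomness flows from one root seed through a fixed integer mixer
  (`generate_session()` block seeds, fold shuffles, subject draws), so any
  component is reproducible in isolation; equal seeds give bit-identical
  recordings.
* Degenerate inputs fail loudly: an all-zero recording cannot be
  normalized; a flat signal segments to an empty list (not an error); a
  class with fewer than two rows refuses LDA/QDA training; saturated
  samples come back `NA` from inverse calibration; a calibration session
  missing a gesture class is an explicit error.
* CSV I/O prints doubles with 17 significant digits, so recordings and
  databases round-trip exactly; model JSON round-trips to identical
  predictions.

## Problem sizes

The shipped tests exercise the full-scale defaults (1 kHz, 2 s holds, ten
repetitions, ten subjects) for the study-level checks, and a compressed
timescale (200 Hz, 0.4 s holds) with identical statistical structure for
unit tests; the oracle-agreement suites run twenty seeded databases per
classifier. The complete cohort experiment — all four classifiers, both
cross-validation schemes, ablation, pooling, and the reproducibility test —
runs in a few minutes on one core.

## Worked example

```{r example, eval = FALSE}
profile <- default_activation_profile()
subject <- draw_subject_profile(profile, seed = 101)
session <- generate_session(subject, repetitions = 10, seed = 1,
                            subject_id = "S1")
db <- build_database(session)
table(db$label)

cross_validate(db, train_lda, cv_kfold(10, seed = 42))
cross_validate(db, function(d) train_linear_svm(d), cv_loo())

decoder <- calibration_session(session, function(d) train_linear_svm(d))
fresh <- generate_trial(subject, repetitions = 3,
                        gestures = "clenched_fist", seed = 99)
decisions <- stream_decode(fresh, decoder)
majority_per_plateau(decisions, fresh$timeline)
```
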