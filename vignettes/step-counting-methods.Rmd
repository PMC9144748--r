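---
title: "Position-independent step counting: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-independent step counting: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Smartphone pedometers are unreliable because people carry their phones in
different places — in a hand, a trouser pocket, a handbag — and each
carrying position imprints a different pattern on the accelerometer
signal. A counting rule tuned for one position miscounts in another.
`stepcountr` implements a two-stage remedy:

1. a **carrying-position classifier** decides where the phone is carried
   from short windows of the acceleration magnitude, and
2. a bank of **position-specific step-count regressors** — one set of
   models per position — predicts the number of steps in each window,
   routed by the classifier's decision.

Supervision comes from a single-foot plantar-pressure channel: a
force-sensitive resistor (FSR) under the toe produces a force pulse at
every stance phase, so counting pressure peaks yields step labels
automatically, without manual counting.

## Signal model and preprocessing

**Magnitude.** The tri-axial acceleration $(X, Y, Z)$ (m/s², gravity
included) is collapsed to its Euclidean norm
$\mathrm{SVM} = \sqrt{X^2 + Y^2 + Z^2}$. The norm is invariant under
rotation of the sensor frame, so the downstream models never see the
phone's (unknown and unstable) orientation; gravity is deliberately kept
in the signal, giving each window a stable ~9.81 m/s² operating point.

**Smoothing.** Both streams pass through an equal-weight moving-average
filter, $A_t = (a_{t-2} + a_{t-1} + a_t + a_{t+1} + a_{t+2})/5$. Edge
samples use a symmetrically shrunk window (the centre sample and the $k$
available neighbours on each side), so the output has the input's length,
constants pass through unchanged everywhere, and no phantom zeros are
invented at the boundaries — phantom zeros would look like spurious
pressure troughs to the peak detector.

**Sensor-range clipping.** The FSR is sensitive between roughly 0.5 and
60 N; readings below 0.5 N are set to 0 N and above 60 N to 60 N.
Clipping models the physical sensor, so it is applied *before* the
software smoothing (the order the electronics impose); negative raw
values are treated as below-range.

## Automatic labeling

Step events are upward crossings of a **30 N threshold** subject to a
**0.2 s refractory period**: a crossing closer than 0.2 s to the previous
accepted event is discarded as noise. The threshold sits at half the
sensor range, above nearly all contact noise; the refractory period is
safe because walking cadence (0.5–3 Hz) spaces true peaks at least
~0.33 s apart. We operationalise "peak" as a threshold *crossing* rather
than a local-maximum search: a crossing detector needs no look-ahead,
matches the "zero to non-zero pressure" definition of a step, and the
refractory period already de-duplicates any secondary crossings within a
stance. Event times are the crossing samples' timestamps — at 30 Hz the
~33 ms quantisation is far below the refractory period, so interpolation
would add complexity without information.

Window labels use **half-open** time spans $[t_0, t_0 + 2\,\mathrm{s})$:
an event on a boundary shared by two adjacent windows is counted exactly
once per tiling.

## Sliding windows

Windows are 2 s long with 50% overlap — 60 samples advanced by 30 at the
30 Hz sampling rate — so every window contains at least one full gait
cycle across the whole walking band. Trailing samples that do not fill a
window are dropped, never padded: padding would fabricate signal and
bias the window's label downward. Feature rows are the raw 60 filtered
magnitude samples; the dataset stores nothing else.

Inside the model bank, every algorithm additionally receives three
window summary statistics appended at fit/predict time: the window mean,
its standard deviation, and the number of upward crossings of the window
mean. The crossing count is a cadence proxy that is *linear* in the
quantity being predicted; without it, a linear support-vector regressor
on raw oscillatory samples is phase-blind — any fixed linear functional
of a sinusoid averages to zero over phase — and would degenerate to
predicting the global mean count. Tree and network models are
indifferent to the three extra columns.

## The model bank

| role | algorithm | defaults |
|---|---|---|
| classifier | random forest | 200 trees, unrestricted depth |
| regressor | random forest | 500 trees |
| regressor | SVM | linear kernel, $C = 1$ |
| regressor | MLP | 1 hidden layer, 40 units, decay $10^{-3}$ |
| regressor | histogram gradient boosting | 100 rounds, $\eta = 0.1$, depth 6 |
| regressor | k-nearest neighbours | $k = 5$ |
| regressor | ensemble | weighted mean of SVM, MLP, RF |

The **ensemble model** is the weighted average of the SVM, MLP and
random-forest regressors. The weights default to uniform (1/3 each):
with no stated basis for preferring one component, the maximum-entropy
choice is the least presumptive, and a validation-weighted variant can
be configured through the `ensemble` spec's `weights` hyperparameter.
Ensemble predictions are convex combinations of their (non-negativised)
components, so they always lie inside the components' range.

The MLP here is a single-hidden-layer perceptron (40 units): with only
63 input features and integer targets in 0–6, a deep stack has no
capacity advantage, and a shallow network trains in seconds on a single
CPU. A convolutional network is not part of the bank; on 60-sample
windows the forests and the shallow network already saturate performance
on the data this package targets.

Training is fully seeded: every `model_spec` carries its own seed, and
identical specs on identical data reproduce identical predictions.

## Splitting, routing and aggregation

**Split.** The dataset is split 7:3. The default mode is
*chronological within each recording*: all training windows precede all
test windows, so the 50% overlap can never leak test samples into
training. A *random* window shuffle is also provided, mirroring the
common protocol, but its holdout estimate is optimistic — adjacent
overlapping windows share 30 of 60 samples.

**Routing.** At inference the classifier votes on every window and the
whole recording is routed to the majority position: phone placement is
fixed within a recording, and the majority vote suppresses isolated
misclassifications. Per-window routing remains available behind
`per_window_routing = TRUE` for recordings where the placement might
change.

**Aggregation.** Each window prediction estimates the steps in one 2 s
span, and consecutive windows overlap, so predictions cannot simply be
summed. The total is the coverage-corrected sum
$\hat N = \mathrm{round}\!\left(\frac{\sum_w \hat y_w}{k}\cdot
\frac{(k-1)\,s + L}{L}\right)$ for $k$ windows of length $L$ and stride
$s$: the mean per-window step rate times the span the windows cover.
In the interior this equals $\sum_w \hat y_w \cdot s/L$ (half the sum at
50% overlap); for a single window it reduces to the window's own
prediction; and it is unbiased at the recording edges, where plain
$\sum/2$ undercounts by up to half a window.

## Evaluation

Step-count accuracy is
$\left(1 - \frac{|N_e - N_r|}{N_r}\right) \times 100\%$, with $N_e$ the
estimated and $N_r$ the real count. It is symmetric in over- and
undercounts of equal size, 100 only for a perfect estimate, and
deliberately **unclamped**: an estimate exceeding $2 N_r$ goes negative,
and the report renders such values with a footnote rather than hiding
them at zero. Report tables aggregate with the unweighted mean of
per-recording accuracies per (position, algorithm) cell, then take
arithmetic marginals; values are stored at full precision and rounded to
one decimal only for display.

## The synthetic gait simulator

The package's recordings are simulated (`generate_walk()`), since no
public corpus pairs smartphone acceleration with single-foot plantar
pressure. One scenario produces:

* **Acceleration** — gravity (9.81 m/s²) on a position-specific axis,
  plus a quasi-periodic component at the cadence and its second
  harmonic, plus i.i.d. Gaussian noise (0.3 m/s² per axis by default).
  The three position signatures are *invented and documented as
  synthetic*: handheld is low-amplitude and smooth (1.2 m/s²
  fundamental), pocket is energetic with a strong second harmonic
  (3.0 + 2.0 m/s²), handbag carries a slow pendulum-like amplitude
  modulation (0.25 Hz, 40% depth). They were chosen once, to be
  statistically separable the way real positions are reported to be —
  not to reproduce any measured waveform.
* **Pressure** — one half-sine stance pulse per step (peak 50 N by
  default, stance fraction 0.6 of the gait cycle, zero during swing), a
  0.15 N sensor noise floor, and optional spurious artifacts: 0.1 s
  bumps of 5–25 N, Poisson-placed at a configurable per-minute rate
  *inside swing gaps only* (≥ 0.1 s clear of stance pulses). Pressure
  noise in this setting comes from foot grazes while the foot is
  airborne, so swing placement is the faithful model; it also guarantees
  that sub-threshold artifacts can never stack onto a stance tail and
  re-cross the 30 N threshold.
* **Ground truth** — the exact pulse onset times. One pulse equals one
  labeled step (`steps_per_peak = 1`); whether a single-foot peak should
  count as one step or one stride is ambiguous in general, and the
  `steps_per_peak` knob records that ambiguity instead of guessing.

Cadence is restricted to the 0.5–3 Hz walking band; the default 1.8 Hz
matches self-paced walking at roughly 0.8–1.5 m/s. Timestamps are
13-digit epoch milliseconds, evenly spaced by default with an optional
jitter knob for exercising timestamp alignment.

**What passing tests do and do not show.** The simulator produces
stationary, noise-controlled, perfectly-labeled walking. Passing the
recovery benchmarks shows the pipeline is implemented correctly and that
the two-stage design recovers known structure; it does *not* show that
the specific accuracy figures transfer to real phones, real gaits,
pauses, turns, or position changes mid-recording. Accuracies on
synthetic cohorts (typically 97–100% in the shipped benchmark) should
therefore be read as an upper bound on what comparable real recordings
would give, as expected for clean simulated signals.

## Benchmark problem sizes

`benchmark_step_counter()` runs the full study protocol at a desk-scale
size chosen as three recordings per position (cadences 1.2, 1.8,
2.4 Hz) of 7 minutes each — about 21 minutes of signal per position,
~3,800 windows in total, leaving 150–300 held-out steps per recording
after the 7:3 chronological split. This is large enough for stable
accuracy estimates on every cell of the report while training the whole
bank in a few minutes on one CPU. The labeler-fidelity grid uses
10-minute recordings over 3 positions × {0.8, 1.5, 2.5} Hz × 5 seeds.

## Numerical and degenerate-input choices

* Filter edges: symmetric shrinking window (see above); `half_width = 0`
  is the identity; an empty trace smooths to an empty trace.
* Stream alignment pairs samples by nearest timestamp within 50 ms,
  drops (and warns about) wider-skewed pairs, enforces injective
  pairing, and fails loudly when spans do not overlap.
* Classifier ties in the majority vote resolve to the first position in
  the canonical order (handheld, pocket, handbag) — deterministic, and
  irrelevant in practice since votes are near-unanimous.
* Predictions are floored at zero before and after ensemble weighting;
  counts cannot be negative.
* `step_accuracy()` refuses $N_r = 0$ rather than dividing by zero.
* CSV values are written with 17 significant digits, so write → read
  round-trips doubles exactly.

## Known limitations

* The simulator is not a biomechanical model: no double-support
  asymmetry, no speed drift within a recording, no running or stairs.
* A single foot is instrumented; if the application defines a "step" as
  either foot's contact, labels from one insole undercount by half
  (see `steps_per_peak`).
* The classifier has a closed world of three positions and no rejection
  class: any window, however atypical, is assigned one of the three.
* Model bundles are serialized R objects; they are versioned and loading
  refuses foreign or future formats, but they are not portable across
  package major versions.
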