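---
title: "Detecting and classifying boxing punches from wrist IMU streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying boxing punches from wrist IMU streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A boxer wears one 6-DoF inertial sensor on each wrist (3-axis accelerometer,
±16 g; 3-axis gyroscope, ±2000 deg/s; 200 Hz). From each wrist's stream we
want, per bout: which windows of the signal contain a punch, each punch's
start and end time, its type (jab, hook or uppercut), per-type counts, and —
when a synchronized video exists — the frame range of every punch so the
clips can be cut out automatically for coaching review.

The expensive part of building such a system is not the modeling but the
labeling: at 200 Hz a few minutes of sparring is tens of thousands of
windows, and conventional supervised training wants 70–80% of them
annotated against video. The core of this package is therefore a pool-based
*query-by-committee* (QBC) active-learning loop that reaches near-ceiling
accuracy with roughly 15% of the windows labeled.

## Pipeline

1. **Windows.** A rolling window of 180 samples (0.9 s, the upper range of
   a punch's duration) slides over the stream, by default with stride 1
   (179-sample overlap). Stride is configurable because stride 1 is wasteful
   for long sessions; all window geometry is half-open in sample indices.
2. **Features** (`extract_features()`). Per window and channel: nine
   time-domain statistics (mean, SD, max, min, IQR, signal entropy,
   skewness, excess kurtosis, mean absolute deviation) and five spectral
   summaries from a Welch PSD (total power, dominant frequency, and band
   powers over 0–5, 5–15 and 15–50 Hz) — 84 features plus the window's time
   span. The axis structure matters: jabs carry their energy on x, hooks on
   y, uppercuts on z.
3. **Labels** (`label_windows()`). A window is a "punch" window when at
   least 60% *of a punch* (denominator: the punch's duration, not the
   window's) falls inside it; its type label is the type of the
   best-overlapping event. The criterion is tunable over [0.1, 1]; the
   punch-labeled sets are provably nested as it rises.
4. **Committee** (`fit_committee()`). Three weak learners: Gaussian naive
   Bayes, a CART decision tree (Gini criterion, at most 100 internal
   splits), and k-nearest-neighbours (Euclidean, k = 5). Their posteriors
   are soft-averaged and renormalized.
5. **Active learning** (`qbc_loop()`). Seed with a random stratified 5% of
   the pool, then repeatedly: fit the committee, score the unlabeled pool
   by the Shannon entropy (bits) of the averaged posterior, query the 5%
   most uncertain windows from the oracle, and stop at 15% labeled — three
   labeling stages in total under the defaults.
6. **Hierarchical inference** (`detect_events()`). A binary committee
   labels windows punch/no-punch; the sequence is smoothed (below); maximal
   runs of 1's become events; a 3-class type committee labels the event's
   windows, and the event takes the *mode* of those labels.
7. **Video cut list** (`segment_video()`). Both devices carry UTC anchors;
   the constant offset between the IMU session clock and the video clock
   maps event times to 0-based frames, `frame = floor(video_time * fps)`,
   emitted as half-open frame ranges.

## Temporal smoothing

Raw per-window predictions flicker near punch boundaries. `smooth_labels()`
applies two rules, in a fixed order, both expressed in seconds:

* fill every *interior* run of 0's shorter than `min_gap_s` (0.2 s) — a
  punch interrupted by a blip of misclassified windows is one punch, and
  two punches closer than a credible inter-punch interval are treated as
  one;
* then delete every run of 1's shorter than `min_event_s` (0.2 s) — too
  short to be a punch.

Leading and trailing 0-runs are never filled. The order is load-bearing
(deleting first can re-open gaps that filling would have bridged), and the
procedure is idempotent. `avg_event_s` (0.8 s, the nominal punch duration)
is carried in configuration for reporting; it is not a smoothing
constraint.

A run of k windows is assigned duration `k * stride / fs`: the label
sequence is read as a piecewise-constant function that holds each window's
label for one stride.

## The synthetic-session generator

Annotated wrist-sensor boxing recordings are not publicly available, so
the package ships a first-class generator (`generate_session()`) that
reproduces the statistical structure the pipeline relies on:

* punches are half-sine acceleration bursts (peak 8 g) on the type's
  dominant axis with a smaller full-sine component on the other two axes
  and a correlated gyroscope burst (peak 600 deg/s); any waveform with the
  right axis-dominance would do, this one is zero-anchored at the ends and
  easy to reason about;
* durations are uniform in 0.8 ± 0.1 s. (Descriptions of the punch vary
  between a 0.9 s average — hence the 180-sample window — and a 0.8 s
  average used for labeling and smoothing; the generator spans both.);
* background guard/bounce motion is band-limited (< 5 Hz) noise with peaks
  under 20% of the punch peak, plus white sensor noise (SD 0.3 g
  accelerometer, 15 deg/s gyroscope);
* non-combo punches are separated by at least `min_gap_s` (0.5 s); with
  probability `combo_prob` a punch is followed within 0.05–0.2 s,
  generated as two distinct ground-truth events so the rapid-combination
  under-count is reproducible;
* the same configuration (including seed) is bit-identical.

What the generator does **not** emulate: biomechanical limb dynamics,
stance (orthodox/southpaw) asymmetries, sensor drift or clipping,
non-punch arm actions (blocks, feints) that share punch-like energy. The
synthetic background separates from punches more cleanly than real guard
motion does, so passing tests bound the pipeline's logic, not its accuracy
on real recordings.

## Design choices in the open corners

* **One window grid.** The labeling criterion is phrased against the
  0.8 s (160-sample) nominal punch while the feature window is 180
  samples; per-window features and labels must correspond one-to-one, so
  a single (configurable, default 180) grid serves both, and the overlap
  denominator is always the punch's own duration.
* **Clock offset sign.** The sync offset is `imu_time − video_time`
  (equivalently `v0_utc − t0_utc` with session-relative stream times): a
  camera started 7 ms after the sensor gives offset +0.007 s, matching the
  observed 1.690 s-vs-1683 ms correspondence between the two displays.
  Drift between the clocks is assumed zero.
* **Event anchoring.** An event's start is its first window's *start* time
  and its end the last window's *end* time (the default). With a 0.9 s
  window this stretches events by roughly the window length, and two events
  closer than that can have overlapping spans even though their window runs
  are disjoint; `anchor = "center"` (first-to-last window centers) gives
  tighter, non-overlapping spans whose width tracks the true punch.
* **Classification stage is 3-class.** The recognition stage already gates
  out background, so the type committee trains on punch-labeled windows
  only. Training it 4-class over all windows starves minority punch types
  at a 15% budget (5% of thirty-odd windows is one sample).
* **Stratified seeding by type.** The initial 5% draw is stratified by the
  finest ground-truth classes available (no-punch/jab/hook/uppercut, when
  a simulated oracle provides them). With coarser strata a draw can miss a
  punch type entirely; the committee is then *confidently* wrong on it and
  entropy ranking never queries it.
* **Consensus entropy.** Uncertainty is the entropy of the averaged
  committee posterior (average first, then score); vote-entropy variants
  are deliberately out of scope.
* **Batch-per-round querying.** Each round queries one 5% batch and refits
  once, rather than refitting after every single label.
* **Evaluation never touches the pool.** The unlabeled 95% is only a query
  pool; held-out metrics come from a separate session, so oracle answers
  cannot leak into the test set.
* **Naive-Bayes details.** Per-feature Gaussian class-conditionals with
  maximum-likelihood variances floored at 1e-9; features are standardized
  (train-set mean/SD) for the naive-Bayes and kNN members — unstandardized
  Euclidean distance would be dominated by the large-magnitude spectral
  features — while the tree sees raw features.
* **Degenerate statistics.** Constant windows define SD/IQR/MAD/entropy/
  skewness/kurtosis as 0 (entropy is that of a 16-bin histogram of the
  window's values); an all-zero channel has all spectral features 0. No
  feature vector ever contains NaN or Inf.
* **Metrics.** Macro-averaged precision and recall; F1 is the harmonic
  mean of the macro pair, with the 0/0 := 0 convention per class.

## Known limitations

* Rapid **same-type** repeats (gap ≤ 0.2 s) merge into one detected event:
  transitional windows carry mostly punch content and are predicted as
  punch, and the minimum-gap rule finishes the merge. This under-count is
  designed behavior, not a bug. Rapid **cross-type** combinations (e.g.
  jab → hook at 0.15 s) often remain separable, because their transitional
  windows mix two axis signatures and the zero-labeled gap between the
  runs survives at just over 0.2 s.
* Event boundary accuracy is limited by the window length: punch onsets
  blend into the guard phase, and the default anchoring widens events by
  design.
* Lead- and rear-hand streams are processed independently; cross-hand
  overlap is allowed and unchecked.

## Problem sizes used in the tests

The shipped tests and the acceptance script run entirely on generated
sessions: 30 s sessions with 8 punches (stride 10, about 580 windows per
session) for the learning-curve and committee studies, 10 session pairs
for the QBC-vs-random comparison, 20 independent 15 s sessions for
event-count verification, and 1000 randomized label sequences for the
run-extraction and smoothing property checks. These sizes were chosen so a
full check runs in minutes on one core while keeping every class of punch
represented dozens of times.
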