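---
title: "Event classification methods in gazekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event classification methods in gazekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazekit)
```

Screen-based eye trackers report a stream of gaze coordinates at a fixed
rate. Nearly every analysis downstream — dwell time on a face, latency to
orient to a peripheral stimulus, number of fixations during visual search —
depends on segmenting that stream into *fixations* (periods of relatively
stable gaze, typically 150–300 ms, during which visual information is
processed) and *saccades* (rapid ballistic movements between them). The
choice of event-classification algorithm and its parameters can change study
outcomes substantially, particularly for noisy recordings from infants or
clinical populations, so gazekit implements four standard classifiers behind
one common interface, together with the pre- and post-processing rules,
quality metrics, and agreement statistics needed to compare them on a given
data set.

Because real clinical recordings are rarely shareable, the package also
ships a scanpath simulator with exact per-sample ground truth. Every claim
this vignette makes about classifier behaviour is one the package's test
suite actually computes on simulated data.

## Units, containers, and conventions

All classification happens in **degrees of visual angle** and
**milliseconds** — the units in which standard thresholds (30°/s, 1°,
60 ms) are defined. `read_gaze_table()` ingests delimited text with a
column map; `pixels_to_degrees()` converts pixel data using a
`screen_geometry()` (per-axis arctangent about the screen center — exact and
monotone, not the small-angle approximation; the choice matters only
peripherally but must be fixed for reproducibility). Screen-proportion data
converts through pixels. Timestamps are re-based to 0 at the first sample.

A recording is a tibble of `time_ms`, `x`, `y`, `valid`, `interpolated`.
Invalid samples (blinks, tracking loss) have undefined coordinates.
Classified events are tibbles too, so the whole surface composes with dplyr
and the pipe. Per-sample angular velocity is the Euclidean displacement over
the inter-sample interval, assigned to the *later* sample of each pair so
that run-grouping has an unambiguous onset convention; velocity is undefined
at the first sample and wherever either bounding sample is invalid, and an
undefined velocity can never extend a saccade across a data gap.

## Pre-processing

`preprocess_gaze()` interpolates gaps and then smooths:

* **Gap interpolation** (`max_gap_ms`, default 75 ms): a maximal invalid run
  flanked by valid data on both sides is filled linearly in time. Each
  anchor is the mean of the valid samples within `margin_ms` (default
  10 ms) of the gap edge, so a single noisy sample adjacent to a blink does
  not tilt the fill. Interpolated samples are marked `valid` for analysis
  but keep an `interpolated` flag: `proportion_data_loss()` counts them as
  lost, because data loss is a property of the recording, not of the
  cleaned copy. Longer gaps stay invalid — interpolating across a long blink
  can fabricate fixations that never happened.
* **Smoothing** (`smooth_window_ms`, default 15 ms): a centered moving
  median (default) or moving average per axis. Windows truncate at
  recording edges and at invalid runs rather than padding — padding invents
  data. The median preserves saccade edges better; the average suppresses
  Gaussian noise slightly more but blurs rapid shifts and delays their
  apparent timing, which is visible in a time-series overlay of raw and
  processed coordinates.

`downsample_gaze()` block-averages by an integer factor (anti-aliasing by
mean, not decimation) — this is also the primitive the two-means clustering
classifier uses internally for its low-rate variants.

## The four classifiers

**I-VT** (`classify_ivt()`). Samples with velocity above
`velocity_threshold_dps` (default 30°/s; 20–40 is the conventional range)
are saccadic; maximal runs become events. Saccade runs shorter than
`min_saccade_ms` (10 ms) are relabeled as fixation context, fixations
shorter than `min_fixation_ms` (60 ms) are dropped, and — crucially for
low-quality data — fixations whose proportion of originally-missing samples
exceeds `missing_samples_threshold` (default 0.5) are dropped. Without that
filter, a fast shift into a long gap is labeled "saccade, then fixation",
and phantom fixations appear inside periods with almost no data. The filter
default is prominent because it changes results dramatically on lossy
recordings.

**I-DT** (`classify_idt()`). A greedy scan grows a candidate fixation while
each incoming valid sample stays within `dispersion_threshold_deg` (default
1°, about half the foveal extent) of the running centroid of the included
valid samples; a violation emits the candidate (if it meets the duration
and missing-proportion rules) and restarts at the violating sample.
Inter-fixation intervals are reported as saccades *without* velocity
metrics — dispersion algorithms do not measure velocity — so AOI and
latency analyses work uniformly across classifiers.

**Adaptive velocity threshold** (`classify_adaptive()`). The peak-saccade
threshold is calibrated to the recording's own noise by iterating
`PT ← mean(v | v ≤ PT) + λ·sd(v | v ≤ PT)` (λ default 6, inclusive
comparison so a zero-variance trace is its own fixed point) from
`initial_peak_threshold_dps` (default 200°/s) until successive values
differ by less than 1°/s. Each run of velocities above the converged
threshold is a saccadic peak; the saccade onset is found by walking
backwards to the first sample below a local noise threshold
(mean + `onset_lambda`·sd of the velocities in the `noise_window_ms` before
the peak), and the offset by walking forwards to the first sample below a
weighted combination (`offset_weight_alpha`, default 0.7) of the onset
threshold and the post-saccadic noise threshold. Fixations are the
inter-saccade intervals, subject to the duration and missing filters.

One numerical subtlety is worth stating explicitly. The fixed-point update
can admit several solutions: the noise-adapted threshold the algorithm is
after, and higher, saccade-contaminated ones — in the extreme a "threshold"
above the global velocity maximum under which nothing is ever classified.
On very clean, saccade-dense recordings the default start of 200°/s can lie
in a contaminated basin. Since the algorithm's stated purpose is to adapt
the threshold to *noise*, `classify_adaptive()` also runs the iteration
upward from the median velocity — which approaches the noise-adapted fixed
point from inside the noise mass — and uses the lower of the two converged
thresholds. The primitive `adaptive_peak_threshold()` performs the plain
iteration only, and the tests verify it against an independently coded
fixed-point iteration to 1e-9.

**I2MC** (`classify_i2mc()`). Designed for noisy, gappy data: a sliding
window (`window_ms` 200, stride `step_ms` 20 — the stride is the
conventional tenth of the window, exposed as a parameter) is clustered into
two groups by k-means on (x, y), at the native rate and after block
downsampling by factors 2, 5, and 10. A window that brackets a
fixation-to-fixation transition separates cleanly, and the sample where the
cluster assignment switches earns weight 1/(switches in that window);
switches found at a coarse rate are assigned to the first native sample of
their block. Per-sample weights are averaged over every window and rate
variant covering the sample, and samples above
`mean + weight_cutoff_sd·sd` (cutoff 2) of the weights are transitions.
Fixation candidates between transitions are first merged (0.7°, 30 ms) and
then duration-filtered — merging first lets fragments cut by scattered
transition samples rejoin their fixation instead of being discarded.
Windows with under `min_valid_prop_window` (0.5) valid samples are skipped,
which is what makes the algorithm degrade gracefully under heavy loss.
Clustering is deterministic: the two seeds are the means of the window's
first and second halves, so a transition window starts well separated and
Lloyd's iterations converge identically on every run — no random restarts,
bit-reproducible output.

## Post-processing

`merge_adjacent_fixations()` repeatedly joins consecutive fixations whose
centroids lie within `max_dist_deg` and whose gap is at most `max_gap_ms`,
chronologically with an immediate re-test, so chains collapse against the
running duration-weighted centroid. The merged *span* absorbs the gap (its
duration grows) while `sample_time_ms` stays the sum of the constituents'
sample time — both are reported because "total fixation time" can mean
either, and the distinction matters when merging is used to undo
noise-induced splitting. Saccades wholly inside a merged span are removed.
`trim_fixations()` shaves `trim_ms` from each fixation edge (samples that
may belong to the saccade), dropping fixations trimmed to nothing.
`drop_fixations()` applies duration / missing-proportion / saccade-amplitude
discard rules; short-fixation (< 60 ms) and small-saccade (< 1°) discards
are conventional.

## Quality and agreement metrics

`proportion_data_loss()` is the fraction of originally-missing samples.
`rmsd_precision()` is the root-mean-square of consecutive-valid-sample
displacements; for i.i.d. isotropic Gaussian noise with per-axis SD σ the
expectation is 2σ (each axis difference has SD σ√2, and there are two
axes), which is how the simulator calibrates its noise parameter.

`compare_event_streams(a, b)` implements relative timing offset/deviation:
each fixation of the reference stream matches the first unused comparison
fixation whose onset and offset lie within the reference interval extended
by `margin_ms` (15 ms); matching is one-to-one so a long fixation cannot
absorb several. RTO is the mean and RTD the n−1 standard deviation of the
matched onset (offset) differences, signed comparison − reference (the sign
convention is stated in the output so "negative RTO" is unambiguous). SD is
reported missing with fewer than two matches, never zero.
`event_recovery_f1()` scores a classifier against simulator truth by greedy
one-to-one overlap matching (a pair counts when it covers at least half of
the shorter event), giving the precision/recall/F1 used in the robustness
comparison. `summarize_algorithms()` tabulates per-algorithm fixation
counts, durations, within-fixation RMSD, and missing proportions — the
descriptive columns used when choosing an algorithm.

## Areas of interest

AOIs are named rectangles or ellipses with inclusive boundaries, defined
programmatically (`aoi_rectangle()`, `aoi_ellipse()`) and serialized as
JSON. `aoi_test()` works in fixation mode (membership by centroid by
default; any-sample and majority-sample strategies are available when the
recording is supplied) or sample mode (dwell proportion of valid samples,
with an explicit `"(outside)"` row so disjoint proportions sum to 1).
Latency to the first fixation inside (or outside) an AOI is measured from
segment start and only counts fixations beginning inside the segment;
fixations already in progress contribute clipped time but not latency, and
undefined latencies are reported missing, never zero. Overlapping AOIs are
permitted and flagged. Interactive on-screen AOI drawing is out of scope;
`plot_fixations_2d()` over a stimulus background serves for visual checking.

## The simulator and what passing tests mean

`simulate_gaze()` renders a declarative `sim_spec()`: fixations are planned
positions plus isotropic Gaussian noise whose per-axis SD is
`noise_rms_deg / 2` (so the parameter *is* the expected RMSD); saccades
follow a raised-cosine displacement profile — unimodal velocity, zero
endpoint velocity — with a main-sequence-style duration of
`21 + 2.2 × amplitude` ms by default, which puts peak velocities above
100°/s from 2° amplitude upward, comfortably above every printed threshold.
Loss is modelled as explicit invalid runs (blinks, look-aways) plus i.i.d.
per-sample loss. Output is bit-identical given the seed.

Two presets pin the study conditions used throughout the tests:
`"clean-1200hz"` (1200 Hz, RMSD 0.12°, ~1.2% loss — a high-quality adult
recording on a research-grade tracker) and `"noisy-lossy"` (1200 Hz, RMSD
0.36°, ≈60% total loss from 100–400 ms blink-like runs at 200–400 ms
intervals plus 25% scattered loss — the low-quality regime typical of
participants with neurodevelopmental conditions). The blink-run/scatter
split is the package's choice of a realistic loss structure at that total
rate; purely i.i.d. loss at 60% would be almost fully repaired by gap
interpolation and would not represent the clinical regime.

The simulator emulates stable fixations, smooth stereotyped saccades, and
loss; it does **not** emulate smooth pursuit, drift, microsaccades,
glissades, calibration offsets, or heteroscedastic noise. Tests passing on
simulated data therefore demonstrate algorithmic correctness under the
stated model, not performance on any particular real data set.

## Problem sizes and numerical choices

The test suite validates: exact agreement of I-VT sample labels with
brute-force thresholding on 200 random traces (250–1200 Hz, noise up to
0.5° RMS); the adaptive threshold against an independent fixed-point
iteration to 1e-9 on 50 traces; I2MC transition locations against a
hand-coded windowed-clustering oracle on 20 noisy lossy traces (two
fixations, 250 Hz) to within one window stride; ground-truth recovery of a
10-fixation 1000-Hz scanpath at 0.05° noise; a 50-seed robustness contrast
in the noisy-lossy regime; and a structural property suite (ordering,
disjointness, translation invariance, merge idempotence, self-comparison)
over more than a thousand randomized cases. These sizes keep the whole
suite around a minute on one CPU while leaving each comparison
statistically meaningful.

Known behaviour worth noting when interpreting the recovery results, both
consequences of algorithm structure rather than implementation choices:

* **I-DT boundary drag.** The greedy centroid rule keeps absorbing saccade
  samples until the eye has moved a full dispersion threshold away, so each
  fixation offset extends, and the next onset begins, roughly the time the
  eye spends inside the last ~1° of the saccade (≈9–13 ms for 2–10°
  amplitudes at the default threshold). Counts are recovered exactly;
  boundary timing is systematically biased. Trimming
  (`trim_fixations()`) exists precisely to counteract this class of bias.
* **I2MC timing granularity.** Transitions localize near the saccade
  midpoint with a blur set by the window stride and the coarsest
  downsampling factor, so fixation boundaries carry a bias of roughly half
  a saccade duration (±10–20 ms here). The algorithm's strength is robust
  *detection* under noise and loss — in the noisy-lossy regime its median
  recovery F1 is several times that of the fixed 30°/s threshold — not
  millisecond-accurate boundary timing.

## Pipeline and reproducibility

`run_pipeline()` executes read → convert → preprocess → classify (one or
several algorithms) → postprocess → summaries/comparisons → optional AOI
statistics and plots from a validated configuration (a named list or
YAML/JSON file; unknown keys are rejected and the input path is checked
before any computation). Every product is written under one output
directory, and a JSON manifest records the package version, the full
parameter set, and an MD5 hash of every output, so an identical
configuration on identical input reproduces identical hashes. All stage
defaults equal the conventional printed values (30°/s, 60 ms, 200°/s, λ=6,
200-ms window, factors 2/5/10, cutoff 2, 0.7°/30 ms, 0.5°/75 ms,
75 ms/15 ms pre-processing). The package exposes no shell entry point: it
is an R-native toolkit, and the exported functions plus this configuration
surface are its interface.

## Limitations

Single gaze stream only (binocular input is averaged at read time); no
smooth-pursuit or microsaccade classification; no glissade labeling; no
spatial-accuracy estimation (that requires known target positions); no 3D /
head-mounted geometry. Animated scanpaths are rendered as deterministic PNG
frame sequences; assembling them into a GIF or video is left to external
encoders.
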