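# gazekit

Fixation and saccade classification for screen-based eye-tracking data, with
the tooling needed to *choose* a classifier, not just run one.

Most eye-tracking analyses — dwell time on a face, latency to orient to a
peripheral stimulus, fixation counts during search — depend on segmenting
the raw gaze stream into **fixations** (stable gaze, typically 150–300 ms)
and **saccades** (rapid ballistic shifts between them). The segmentation
algorithm and its parameters can change study outcomes, especially for
noisy recordings from infants or clinical populations. gazekit implements
four standard event classifiers behind one tidyverse-style interface:

| Classifier | Idea | Key default |
|---|---|---|
| `classify_ivt()` | samples with angular velocity `v > threshold` are saccadic | 30°/s |
| `classify_idt()` | fixations are runs staying within a radius of their running centroid | 1° |
| `classify_adaptive()` | peak threshold iterated to `mean + λ·sd` of sub-threshold velocities, then on/offset searches against local noise | PT₀ = 200°/s, λ = 6 |
| `classify_i2mc()` | sliding-window two-means clustering at several sampling rates; fixations lie between high-weight transition samples | 200-ms window, factors 2/5/10 |

Around them: pre-processing (gap interpolation ≤ 75 ms, moving
median/average smoothing, block-average downsampling), post-processing
(merge close fixations, trim saccade-contaminated edges, discard unlikely
events), data-quality metrics (sample-to-sample RMSD precision, proportion
of data loss), cross-algorithm agreement (relative timing offset/deviation,
RTO/RTD, with a 15-ms matching margin), AOI statistics (fixation counts,
dwell time, entry latencies for rectangles/ellipses), and ggplot2
visualizations of every intermediate. A scanpath simulator with exact
ground truth (`simulate_gaze()`) makes the whole pipeline testable without
access to participant data.

All classification operates in degrees of visual angle and milliseconds;
`pixels_to_degrees()` converts pixel data given a `screen_geometry()`.

## Worked example

Simulate a low-quality recording (sample-to-sample RMSD 0.36°, ≈60% data
loss from blink-like gaps plus scattered dropout — the regime typical of
participants with neurodevelopmental conditions), then compare the fixed
velocity threshold against two-means clustering:

```r
library(gazekit)

sim <- simulate_gaze(sim_spec_preset("noisy-lossy", seed = 42))
proportion_data_loss(sim$recording)
#> [1] 0.527

rec <- preprocess_gaze(sim$recording)   # interpolate <=75 ms gaps, 15 ms median
ev_ivt  <- classify_ivt(rec)
ev_i2mc <- classify_i2mc(rec)

glance(ev_ivt)
#> # A tibble: 1 × 7
#>   algorithm n_fixations n_saccades mean_fixation_ms total_fixation_ms ...
#> 1 ivt                 3          6             345.             1034.
glance(ev_i2mc)
#> 1 i2mc                5          4             212.             1062.
```

The truth table contains 10 fixations. Against it, the fixed threshold
recovers 3 (recall 0.30) while the clustering classifier recovers 5
(recall 0.50) — both with perfect precision:

```r
event_recovery_f1(ev_ivt,  sim$truth_events)   # f1 = 0.462
event_recovery_f1(ev_i2mc, sim$truth_events)   # f1 = 0.667
```

Agreement between the two classifiers, and AOI statistics from the
clustering output:

```r
compare_event_streams(ev_ivt, ev_i2mc)
#>   rto_onset_ms rtd_onset_ms rto_offset_ms rtd_offset_ms n_matched ...
#> 1         92.8         152.          3.33          3.33         3

aois <- dplyr::bind_rows(
  aoi_rectangle("left",  -12, -12,  0, 12),
  aoi_rectangle("right", 1e-4, -12, 12, 12))
aoi_test(ev_i2mc, aois)
#>   name      n_fixations total_fixation_time_ms latency_first_inside_ms
#> 1 left                1                   139.                      0
#> 2 right               4                   923.                    899.
#> 3 (outside)           0                     0                      NA
```

Matched fixations agree to a few milliseconds (RTO_offset 3.3 ms) while the
large onset RTO reflects the threshold classifier's truncation of fixations
around data gaps — exactly the kind of discrepancy the comparison tooling
is meant to surface. `plot_timeseries()`, `plot_fixations_2d()`,
`plot_velocity()`, `plot_algorithm_quality()` and `scanpath_plot()`
visualize each step; `run_pipeline()` drives the whole chain from a YAML/
JSON configuration and writes a manifest with MD5 hashes of every output.

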