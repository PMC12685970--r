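Package: gazekit
Title: Fixation and Saccade Classification for Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screen-based eye-tracking analysis: pre-processing of
    raw gaze samples (gap interpolation, smoothing, downsampling), four
    fixation/saccade event-classification algorithms (velocity threshold,
    dispersion threshold, adaptive noise-calibrated velocity threshold, and
    identification by two-means clustering), post-processing rules (merge,
    trim, discard), data-quality metrics (RMS sample-to-sample precision,
    data loss, relative timing offset/deviation between event streams),
    area-of-interest statistics, and ggplot2 visualizations. A synthetic
    scanpath simulator with per-sample ground truth makes every stage of the
    pipeline testable without access to recorded participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
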