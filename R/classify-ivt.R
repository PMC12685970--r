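# Identification by velocity threshold (I-VT): samples whose angular
# velocity exceeds a fixed cutoff are saccadic; inter-saccade periods are
# fixations.

#' Parameters for the velocity-threshold classifier
#'
#' @param velocity_threshold_dps Saccade velocity cutoff, deg/s. Values of
#'   20-40 deg/s are typical for high-quality screen-based data; 30 is the
#'   common default.
#' @param min_fixation_ms Minimum fixation duration; shorter candidates are
#'   dropped as physiologically unlikely.
#' @param min_saccade_ms Minimum saccade duration; shorter above-threshold
#'   runs (usually noise spikes) are relabeled as part of the surrounding
#'   fixation.
#' @param missing_samples_threshold Maximum proportion of originally-missing
#'   constituent samples for a fixation to be kept. Without this filter,
#'   periods of lost data bounded by fast gaze shifts are reported as
#'   spurious fixations. Set to 1 to disable.
#' @param merge Apply the merge rule after classification?
#' @param merge_dist_deg,merge_gap_ms Merge rule: consecutive fixations
#'   within this centroid distance and inter-event gap are merged (see
#'   [merge_adjacent_fixations()]).
#' @param velocity_smooth_window_ms Optional moving-average smoothing of the
#'   velocity trace before thresholding (0 = none).
#'
#' @return A list of class `ivt_params`.
#' @export
ivt_params <- function(velocity_threshold_dps = 30, min_fixation_ms = 60,
                       min_saccade_ms = 10, missing_samples_threshold = 0.5,
                       merge = FALSE, merge_dist_deg = 0.5, merge_gap_ms = 75,
                       velocity_smooth_window_ms = 0) {
  if (velocity_threshold_dps <= 0) stop_param("velocity_threshold_dps must be > 0")
  if (min_fixation_ms < 0 || min_saccade_ms < 0) stop_param("minimum durations must be >= 0")
  if (missing_samples_threshold < 0 || missing_samples_threshold > 1) {
    stop_param("missing_samples_threshold must be in [0, 1]")
  }
  structure(list(velocity_threshold_dps = velocity_threshold_dps,
                 min_fixation_ms = min_fixation_ms,
                 min_saccade_ms = min_saccade_ms,
                 missing_samples_threshold = missing_samples_threshold,
                 merge = merge, merge_dist_deg = merge_dist_deg,
                 merge_gap_ms = merge_gap_ms,
                 velocity_smooth_window_ms = velocity_smooth_window_ms),
            class = "ivt_params")
}

#' Classify fixations and saccades by velocity threshold (I-VT)
#'
#' Labels every sample with a defined velocity above
#' `velocity_threshold_dps` as saccadic and groups maximal same-label runs
#' into candidate events. Saccade runs shorter than `min_saccade_ms` are
#' relabeled to the surrounding fixation context; fixation candidates
#' shorter than `min_fixation_ms`, or with more than
#' `missing_samples_threshold` originally-missing samples, are dropped.
#' Samples with undefined velocity (adjacent to invalid data) never extend a
#' saccade. With `merge = TRUE` in the parameters, the merge rule is applied
#' to the resulting fixations.
#'
#' @param rec A `gaze_recording` in degrees.
#' @param params An [ivt_params()] object.
#' @return An `event_set`.
#' @examples
#' sim <- simulate_gaze(sim_spec(
#'   fixations = data.frame(x_deg = c(0, 5, 0), y_deg = 0,
#'                          duration_ms = 300),
#'   rate_hz = 1000, seed = 1))
#' classify_ivt(sim$recording)
#' @export
classify_ivt <- function(rec, params = ivt_params()) {
  assert_degrees(rec)
  vel <- compute_velocity(rec, params$velocity_smooth_window_ms)
  sacc <- saccade_sample_labels(vel, params$velocity_threshold_dps)
  t <- rec$time_ms

  spans <- run_spans(sacc)
  # relabel short saccade runs into the surrounding fixation context
  short <- spans$value & (t[spans$i1] - t[spans$i0]) < params$min_saccade_ms
  for (k in which(short)) sacc[spans$i0[k]:spans$i1[k]] <- FALSE

  spans <- run_spans(sacc)
  spans$kind <- ifelse(spans$value, "saccade", "fixation")
  events <- build_event_set(rec, spans[, c("i0", "i1", "kind")],
                            algorithm = "ivt", params = unclass(params),
                            vel = vel)
  keep <- events$kind == "saccade" |
    (events$duration_ms >= params$min_fixation_ms &
       events$prop_missing <= params$missing_samples_threshold)
  events <- keep_event_attrs(events[keep, ], events)
  if (isTRUE(params$merge)) {
    events <- merge_adjacent_fixations(events, rec = rec,
                                       max_dist_deg = params$merge_dist_deg,
                                       max_gap_ms = params$merge_gap_ms)
  }
  events
}
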