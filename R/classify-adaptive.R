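# Adaptive (noise-calibrated) velocity threshold classification: the peak
# saccade threshold is iterated to a fixed point of
#   PT <- mean(v | v <= PT) + lambda * sd(v | v <= PT)
# so it adapts to the noise level of each recording, and saccade on/offsets
# are searched backwards/forwards from each peak against locally estimated
# noise thresholds.

#' Parameters for the adaptive velocity-threshold classifier
#'
#' @param initial_peak_threshold_dps Starting value of the peak-velocity
#'   threshold iteration, deg/s.
#' @param lambda Multiplier on the standard deviation of sub-threshold
#'   velocities in the fixed-point update; larger values make the detector
#'   more conservative. Typically 6.
#' @param convergence_tol_dps Iteration stops when consecutive thresholds
#'   differ by less than this, deg/s.
#' @param min_fixation_ms,min_saccade_ms Minimum event durations.
#' @param onset_lambda Multiplier on the local noise standard deviation when
#'   setting the saccade on/offset thresholds.
#' @param offset_weight_alpha Weight `a` in the offset threshold
#'   `a * onset_threshold + (1 - a) * local post-saccade noise threshold`,
#'   in `[0, 1]`.
#' @param noise_window_ms Length of the local window before (after) a peak
#'   used to estimate pre- (post-) saccadic noise.
#' @param missing_samples_threshold Maximum proportion of originally-missing
#'   samples for a fixation to be kept.
#' @param velocity_smooth_window_ms Optional moving-average smoothing of the
#'   velocity trace before thresholding (0 = none).
#'
#' @return A list of class `adaptive_params`.
#' @export
adaptive_params <- function(initial_peak_threshold_dps = 200, lambda = 6,
                            convergence_tol_dps = 1, min_fixation_ms = 40,
                            min_saccade_ms = 12, onset_lambda = 3,
                            offset_weight_alpha = 0.7, noise_window_ms = 40,
                            missing_samples_threshold = 0.5,
                            velocity_smooth_window_ms = 0) {
  if (initial_peak_threshold_dps <= 0) stop_param("initial_peak_threshold_dps must be > 0")
  if (lambda <= 0) stop_param("lambda must be > 0")
  if (offset_weight_alpha < 0 || offset_weight_alpha > 1) {
    stop_param("offset_weight_alpha must be in [0, 1]")
  }
  structure(list(initial_peak_threshold_dps = initial_peak_threshold_dps,
                 lambda = lambda, convergence_tol_dps = convergence_tol_dps,
                 min_fixation_ms = min_fixation_ms,
                 min_saccade_ms = min_saccade_ms, onset_lambda = onset_lambda,
                 offset_weight_alpha = offset_weight_alpha,
                 noise_window_ms = noise_window_ms,
                 missing_samples_threshold = missing_samples_threshold,
                 velocity_smooth_window_ms = velocity_smooth_window_ms),
            class = "adaptive_params")
}

#' Iterate the data-driven peak velocity threshold to its fixed point
#'
#' Repeats `PT <- mean(v | v <= PT) + lambda * sd(v | v <= PT)` (inclusive
#' comparison, so a zero-variance velocity set is its own fixed point) until
#' two consecutive values differ by less than `tol_dps`. Undefined
#' velocities are ignored. If an update would empty the sub-threshold set the
#' previous threshold is kept with a warning; failure to converge within
#' `max_iter` iterations is an error reporting the last two values.
#'
#' @param v Numeric vector of velocities, deg/s (`NA` = undefined).
#' @param pt0 Initial threshold, deg/s.
#' @param lambda Standard-deviation multiplier.
#' @param tol_dps Convergence tolerance, deg/s.
#' @param max_iter Iteration cap.
#' @return The converged peak threshold, with the number of updates in
#'   attribute `iterations`.
#' @export
adaptive_peak_threshold <- function(v, pt0 = 200, lambda = 6, tol_dps = 1,
                                    max_iter = 100) {
  v <- v[!is.na(v)]
  if (length(v) == 0) stop_input("No defined velocities to calibrate a threshold on.")
  pt <- pt0
  for (k in seq_len(max_iter)) {
    sub <- v[v <= pt]
    if (length(sub) == 0) {
      warn("Peak-threshold update emptied the sub-threshold set; keeping the previous threshold.")
      attr(pt, "iterations") <- k - 1L
      return(pt)
    }
    s <- if (length(sub) >= 2) sd(sub) else 0
    new_pt <- mean(sub) + lambda * s
    if (abs(new_pt - pt) < tol_dps) {
      out <- new_pt
      attr(out, "iterations") <- k
      return(out)
    }
    pt <- new_pt
  }
  stop_input(sprintf(
    "Peak-threshold iteration did not converge in %d iterations (last values: %.6f, %.6f).",
    max_iter, pt, new_pt))
}

#' Classify events with the adaptive velocity-threshold algorithm
#'
#' Calibrates the peak saccade-velocity threshold to the recording's noise
#' with [adaptive_peak_threshold()], treats each maximal run of velocities
#' above the converged threshold as a saccadic peak, and then searches
#' backwards from each peak for the saccade onset (the first sample whose
#' velocity drops below a local noise threshold, mean + `onset_lambda` * sd
#' of the velocities in the `noise_window_ms` preceding the peak) and
#' forwards for the offset (first sample below a weighted combination of the
#' onset threshold and the post-saccadic noise threshold). Saccades shorter
#' than `min_saccade_ms` are discarded; fixations are the inter-saccade
#' intervals of at least `min_fixation_ms`, subject to the
#' missing-proportion filter. Undefined velocities stop the on/offset walks
#' (a saccade never extends across a data gap).
#'
#' @param rec A `gaze_recording` in degrees, with at least `noise_window_ms`
#'   of defined velocity.
#' @param params An [adaptive_params()] object.
#' @return An `event_set`.
#' @export
classify_adaptive <- function(rec, params = adaptive_params()) {
  assert_degrees(rec)
  vel <- compute_velocity(rec, params$velocity_smooth_window_ms)
  v <- vel$velocity_dps
  t <- rec$time_ms
  n <- length(v)
  if (sum(!is.na(v)) < 2) stop_input("Not enough defined velocity to classify.")

  pt <- adaptive_peak_threshold(v, pt0 = params$initial_peak_threshold_dps,
                                lambda = params$lambda,
                                tol_dps = params$convergence_tol_dps)
  # The update map can have several fixed points: the noise-adapted one the
  # algorithm is after, and higher ones still contaminated by saccade
  # samples (in the extreme, above the global velocity maximum, so nothing
  # is ever classified). Data much cleaner than the update rule anticipates
  # can put the default starting threshold in a contaminated basin, so the
  # iteration is also run upward from the median velocity — which
  # approaches the noise-adapted fixed point from inside the noise mass —
  # and the lower of the two converged thresholds is used.
  pt_low <- tryCatch(
    adaptive_peak_threshold(v, pt0 = median(v, na.rm = TRUE),
                            lambda = params$lambda,
                            tol_dps = params$convergence_tol_dps),
    error = function(e) NULL)
  if (!is.null(pt_low) && pt_low < pt && any(!is.na(v) & v > pt_low)) {
    pt <- pt_low
  }
  sub <- v[!is.na(v) & v <= pt]
  global_thr <- mean(sub) + params$onset_lambda *
    (if (length(sub) >= 2) sd(sub) else 0)

  local_threshold <- function(idx_window) {
    w <- v[idx_window]
    w <- w[!is.na(w) & w <= pt]
    if (length(w) < 2) return(global_thr)
    mean(w) + params$onset_lambda * sd(w)
  }

  peaks <- run_spans(!is.na(v) & v > pt)
  peaks <- peaks[peaks$value, , drop = FALSE]
  sacc <- matrix(integer(0), ncol = 2)
  for (k in seq_len(nrow(peaks))) {
    p0 <- peaks$i0[k]; p1 <- peaks$i1[k]
    pre_idx <- which(t >= t[p0] - params$noise_window_ms & t < t[p0])
    onset_thr <- local_threshold(pre_idx)
    i <- p0
    while (i > 1L && !is.na(v[i - 1L]) && v[i - 1L] >= onset_thr) i <- i - 1L
    # first sample below the onset threshold; a data gap stops the walk
    onset <- if (i > 1L && !is.na(v[i - 1L])) i - 1L else i
    post_idx <- which(t > t[p1] & t <= t[p1] + params$noise_window_ms)
    offset_thr <- params$offset_weight_alpha * onset_thr +
      (1 - params$offset_weight_alpha) * local_threshold(post_idx)
    j <- p1
    while (j < n && !is.na(v[j + 1L]) && v[j + 1L] >= offset_thr) j <- j + 1L
    offset <- if (j < n && !is.na(v[j + 1L])) j + 1L else j
    sacc <- rbind(sacc, c(onset, offset))
  }

  # overlapping walked spans (several peaks in one saccade) are merged
  if (nrow(sacc) > 0) {
    sacc <- sacc[order(sacc[, 1]), , drop = FALSE]
    merged <- list(sacc[1, ])
    for (k in seq_len(nrow(sacc))[-1]) {
      last <- merged[[length(merged)]]
      if (sacc[k, 1] <= last[2]) {
        merged[[length(merged)]] <- c(last[1], max(last[2], sacc[k, 2]))
      } else {
        merged[[length(merged) + 1L]] <- sacc[k, ]
      }
    }
    sacc <- do.call(rbind, merged)
    sacc <- sacc[t[sacc[, 2]] - t[sacc[, 1]] >= params$min_saccade_ms, ,
                 drop = FALSE]
  }

  # fixations tile the intervals between saccades (boundary samples shared)
  fix <- matrix(integer(0), ncol = 2)
  bounds <- rbind(c(NA, 1L), sacc, c(n, NA))
  for (k in seq_len(nrow(bounds) - 1)) {
    f0 <- bounds[k, 2]; f1 <- bounds[k + 1, 1]
    if (!is.na(f0) && !is.na(f1) && f1 > f0) fix <- rbind(fix, c(f0, f1))
  }

  spans <- dplyr::bind_rows(
    tibble::tibble(i0 = as.integer(sacc[, 1]), i1 = as.integer(sacc[, 2]),
                   kind = rep("saccade", nrow(sacc))),
    tibble::tibble(i0 = as.integer(fix[, 1]), i1 = as.integer(fix[, 2]),
                   kind = rep("fixation", nrow(fix))))
  events <- build_event_set(rec, spans, algorithm = "adaptive",
                            params = c(unclass(params), peak_threshold_dps = as.numeric(pt)),
                            vel = vel)
  keep <- events$kind == "saccade" |
    (events$duration_ms >= params$min_fixation_ms &
       events$prop_missing <= params$missing_samples_threshold)
  keep_event_attrs(events[keep, ], events)
}
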