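# Per-sample angular velocity: the shared input of the velocity-threshold
# and adaptive classifiers.

#' Compute per-sample angular velocity
#'
#' Velocity is the Euclidean distance between two consecutive samples divided
#' by the inter-sample time interval, in degrees per second. Each velocity is
#' assigned to the *later* sample of the pair, which keeps saccade-onset
#' definitions unambiguous when samples are grouped into runs. The velocity
#' is undefined (`NA`) at the first sample and wherever either bounding
#' sample is invalid; classifiers treat undefined velocities as "not above
#' threshold" but never let them extend a saccade across a gap.
#'
#' @param rec A `gaze_recording` in degrees.
#' @param smooth_window_ms Optional centered moving-average window applied to
#'   the velocity trace (0 = no smoothing, the default). Smoothing never
#'   bridges undefined entries.
#'
#' @return A `velocity_trace` tibble with columns `time_ms` and
#'   `velocity_dps`, aligned sample-for-sample with `rec`.
#' @examples
#' rec <- as_gaze_recording(
#'   data.frame(time_ms = 0:10, x = 0.03 * (0:10), y = 0), "deg")
#' compute_velocity(rec)  # 30 deg/s wherever defined
#' @export
compute_velocity <- function(rec, smooth_window_ms = 0) {
  assert_degrees(rec)
  n <- nrow(rec)
  t <- rec$time_ms
  v <- rep(NA_real_, n)
  if (n >= 2) {
    dx <- diff(rec$x); dy <- diff(rec$y); dt <- diff(t)
    vv <- sqrt(dx^2 + dy^2) / dt * 1000
    ok <- rec$valid[-1] & rec$valid[-n] & is.finite(vv)
    v[-1] <- ifelse(ok, vv, NA_real_)
  }
  if (smooth_window_ms > 0 && n >= 2) {
    rate <- recording_rate(rec)
    w <- max(1L, round(smooth_window_ms * rate / 1000))
    if (w %% 2 == 0) w <- w + 1L
    if (w > 1L) {
      r <- rle(!is.na(v))
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in seq_along(r$lengths)) {
        if (!r$values[k]) next
        idx <- starts[k]:ends[k]
        if (length(idx) < 2) next
        ww <- min(w, if (length(idx) %% 2 == 0) length(idx) - 1L else length(idx))
        v[idx] <- zoo::rollapply(v[idx], ww, mean, partial = TRUE, align = "center")
      }
    }
  }
  out <- tibble::tibble(time_ms = t, velocity_dps = v)
  attr(out, "rate_hz") <- if (n >= 2) recording_rate(rec) else NA_real_
  class(out) <- c("velocity_trace", class(out))
  out
}

#' Per-sample saccade labels under a fixed velocity threshold
#'
#' The raw labeling step of the velocity-threshold classifier, before any
#' duration filtering or merging: a sample is saccadic iff its velocity is
#' defined and strictly exceeds the threshold.
#'
#' @param vel A `velocity_trace` from [compute_velocity()].
#' @param threshold_dps Velocity threshold in degrees per second.
#' @return A logical vector, one entry per sample.
#' @export
saccade_sample_labels <- function(vel, threshold_dps) {
  if (threshold_dps <= 0) stop_param("velocity threshold must be > 0")
  !is.na(vel$velocity_dps) & vel$velocity_dps > threshold_dps
}
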