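# Pre-processing of raw gaze before event classification: interpolation of
# short gaps (blinks, tracking dropouts), smoothing, downsampling.

#' Pre-processing parameters
#'
#' @param max_gap_ms Longest invalid run to interpolate, ms. Gaps longer than
#'   this (typically blinks or look-aways) stay invalid.
#' @param margin_ms Length of valid data averaged on each side of a gap to
#'   anchor the interpolation, ms. Averaging over a short flank segment keeps
#'   single noisy samples next to the gap from biasing the anchors.
#' @param smooth_window_ms Length of the centered smoothing window, ms.
#' @param smooth_method `"median"` (robust, default) or `"average"`.
#'
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(max_gap_ms = 75, margin_ms = 10,
                              smooth_window_ms = 15,
                              smooth_method = c("median", "average")) {
  smooth_method <- match.arg(smooth_method)
  if (max_gap_ms < 0 || margin_ms < 0 || smooth_window_ms < 0) {
    stop_param("All pre-processing durations must be >= 0.")
  }
  structure(list(max_gap_ms = max_gap_ms, margin_ms = margin_ms,
                 smooth_window_ms = smooth_window_ms,
                 smooth_method = smooth_method),
            class = "preprocess_params")
}

#' Linearly interpolate short gaps of invalid samples
#'
#' Each maximal run of invalid samples whose spanned duration is at most
#' `max_gap_ms`, and which has at least one valid sample on both sides, is
#' replaced by linear interpolation in time between two anchor points. Each
#' anchor is the mean of the valid coordinates within `margin_ms` adjacent to
#' the gap (falling back to the nearest valid sample if the margin holds
#' none). Interpolated samples are marked `valid = TRUE` and flagged
#' `interpolated = TRUE`, so data-quality metrics can still count them as
#' originally missing. Longer gaps, and gaps touching the recording
#' boundaries, are left untouched. Valid original samples are never modified.
#'
#' @param rec A `gaze_recording`.
#' @param params A [preprocess_params()] object.
#' @return A `gaze_recording` of identical length and timestamps.
#' @export
interpolate_gaps <- function(rec, params = preprocess_params()) {
  assert_recording(rec)
  n <- nrow(rec)
  if (n == 0 || all(rec$valid)) return(rec)
  t <- rec$time_ms; x <- rec$x; y <- rec$y
  valid <- rec$valid; interp <- rec$interpolated

  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    if (i0 == 1L || i1 == n) next               # boundary gap: no anchors
    # the data-free interval spans from the last valid sample before the gap
    # to the first valid one after it
    gap_dur <- t[i1 + 1L] - t[i0 - 1L]
    if (gap_dur > params$max_gap_ms) next
    pre_idx <- which(valid & t >= t[i0 - 1L] - params$margin_ms & t <= t[i0 - 1L])
    post_idx <- which(valid & t >= t[i1 + 1L] & t <= t[i1 + 1L] + params$margin_ms)
    if (length(pre_idx) == 0) pre_idx <- i0 - 1L
    if (length(post_idx) == 0) post_idx <- i1 + 1L
    t0 <- t[i0 - 1L]; t1 <- t[i1 + 1L]
    ax0 <- mean(x[pre_idx]); ay0 <- mean(y[pre_idx])
    ax1 <- mean(x[post_idx]); ay1 <- mean(y[post_idx])
    f <- (t[i0:i1] - t0) / (t1 - t0)
    x[i0:i1] <- ax0 + f * (ax1 - ax0)
    y[i0:i1] <- ay0 + f * (ay1 - ay0)
    valid[i0:i1] <- TRUE
    interp[i0:i1] <- TRUE
  }
  out <- rec
  out$x <- x; out$y <- y; out$valid <- valid; out$interpolated <- interp
  out
}

#' Smooth gaze coordinates with a moving median or average
#'
#' Replaces `x` and `y` by a centered moving median (or average) over a
#' window of `round(smooth_window_ms * rate / 1000)` samples, forced odd
#' (minimum 1). Windows never bridge invalid samples: smoothing is applied
#' within each maximal run of valid samples, truncating at run edges rather
#' than padding. Invalid samples remain invalid and untouched.
#'
#' @inheritParams interpolate_gaps
#' @return A `gaze_recording` of identical length and timestamps.
#' @export
smooth_gaze <- function(rec, params = preprocess_params()) {
  assert_recording(rec)
  n <- nrow(rec)
  if (n == 0) return(rec)
  rate <- recording_rate(rec)
  w <- max(1L, round(params$smooth_window_ms * rate / 1000))
  if (w %% 2 == 0) w <- w + 1L
  if (w <= 1L) return(rec)
  fun <- if (params$smooth_method == "median") median else mean

  x <- rec$x; y <- rec$y
  r <- rle(rec$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    idx <- starts[k]:ends[k]
    if (length(idx) < 2) next
    ww <- min(w, if (length(idx) %% 2 == 0) length(idx) - 1L else length(idx))
    x[idx] <- zoo::rollapply(x[idx], ww, fun, partial = TRUE, align = "center")
    y[idx] <- zoo::rollapply(y[idx], ww, fun, partial = TRUE, align = "center")
  }
  out <- rec
  out$x <- x; out$y <- y
  out
}

#' Interpolate and smooth in one call
#'
#' The standard pre-processing pipeline: [interpolate_gaps()] followed by
#' [smooth_gaze()], both controlled by one [preprocess_params()] object.
#'
#' @inheritParams interpolate_gaps
#' @return A pre-processed `gaze_recording`.
#' @export
preprocess_gaze <- function(rec, params = preprocess_params()) {
  smooth_gaze(interpolate_gaps(rec, params), params)
}

#' Downsample a recording to a lower sampling rate
#'
#' Anti-aliases by block averaging: the native/target rate ratio is rounded
#' to the nearest integer factor `k`, and each consecutive block of `k`
#' samples collapses to one output sample whose coordinate is the mean of the
#' block's valid samples, whose timestamp is the block's first timestamp, and
#' which is valid iff the block holds at least one valid sample.
#'
#' @param rec A `gaze_recording`.
#' @param target_hz Target sampling rate; must not exceed the native rate.
#' @return A `gaze_recording` at the lower rate.
#' @export
downsample_gaze <- function(rec, target_hz) {
  assert_recording(rec)
  native <- recording_rate(rec)
  if (target_hz > native * (1 + 1e-6)) {
    stop_input(sprintf("Target rate (%.1f Hz) is above the native rate (%.1f Hz).",
                       target_hz, native))
  }
  k <- max(1L, as.integer(round(native / target_hz)))
  downsample_by_factor(rec, k)
}

# Integer-factor block averaging; shared by downsample_gaze() and I2MC.
downsample_by_factor <- function(rec, k) {
  k <- as.integer(k)
  if (k <= 1L) return(rec)
  n <- nrow(rec)
  block <- ((seq_len(n) - 1L) %/% k) + 1L
  first_of_block <- !duplicated(block)
  mean_valid <- function(v, ok) {
    out <- tapply(ifelse(ok, v, NA_real_), block, mean, na.rm = TRUE)
    out[is.nan(out)] <- NA_real_
    as.numeric(out)
  }
  xs <- mean_valid(rec$x, rec$valid)
  ys <- mean_valid(rec$y, rec$valid)
  valid <- as.logical(tapply(rec$valid, block, any))
  interp <- as.logical(tapply(rec$interpolated & rec$valid, block, any))
  out <- tibble::tibble(
    time_ms = rec$time_ms[first_of_block],
    x = xs, y = ys, valid = valid, interpolated = interp)
  new_gaze_recording(out, unit = gaze_unit(rec), geometry = gaze_geometry(rec),
                     rate_hz = recording_rate(rec) / k)
}
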