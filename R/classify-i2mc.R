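# Identification by two-means clustering (I2MC): a sliding window is
# clustered into two groups by k-means at several sampling rates; windows
# containing a fixation-to-fixation transition separate cleanly into two
# clusters, and the samples where the cluster assignment switches accumulate
# transition weight. Fixations are the periods between high-weight
# transition samples. The multi-rate voting makes the algorithm robust to
# noise and missing data, which is its reason to exist.

#' Parameters for the two-means-clustering classifier
#'
#' @param window_ms Length of the sliding clustering window.
#' @param step_ms Stride between window onsets; each sample is clustered in
#'   many overlapping windows.
#' @param downsample_factors Integer block-averaging factors; clustering is
#'   repeated at the native rate and at each downsampled rate.
#' @param weight_cutoff_sd Transition cutoff: samples whose mean transition
#'   weight exceeds `mean(weights) + weight_cutoff_sd * sd(weights)` are
#'   transition samples.
#' @param merge_dist_deg,merge_gap_ms Post-classification fixation merge
#'   rule (see [merge_adjacent_fixations()]).
#' @param min_fixation_ms Minimum fixation duration.
#' @param min_valid_prop_window Minimum proportion of valid samples for a
#'   window to be clustered.
#' @param missing_samples_threshold Maximum proportion of originally-missing
#'   samples for a fixation to be kept.
#'
#' @return A list of class `i2mc_params`.
#' @export
i2mc_params <- function(window_ms = 200, step_ms = 20,
                        downsample_factors = c(2, 5, 10),
                        weight_cutoff_sd = 2, merge_dist_deg = 0.7,
                        merge_gap_ms = 30, min_fixation_ms = 40,
                        min_valid_prop_window = 0.5,
                        missing_samples_threshold = 0.5) {
  if (!(window_ms > step_ms && step_ms > 0)) {
    stop_param("window_ms must exceed step_ms, and step_ms must be > 0.")
  }
  if (any(downsample_factors < 2) || any(downsample_factors != round(downsample_factors))) {
    stop_param("downsample_factors must be integers >= 2.")
  }
  if (weight_cutoff_sd <= 0) stop_param("weight_cutoff_sd must be > 0.")
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 downsample_factors = as.integer(downsample_factors),
                 weight_cutoff_sd = weight_cutoff_sd,
                 merge_dist_deg = merge_dist_deg, merge_gap_ms = merge_gap_ms,
                 min_fixation_ms = min_fixation_ms,
                 min_valid_prop_window = min_valid_prop_window,
                 missing_samples_threshold = missing_samples_threshold),
            class = "i2mc_params")
}

# Deterministic two-means clustering of a window: the two seeds are the
# means of the window's first and second halves (in time), so a window that
# brackets a transition starts with well-separated seeds and Lloyd's
# iterations converge identically on every run. Returns the assignment
# vector, or NULL when the window cannot be split (identical seeds or a
# degenerate clustering).
two_means_assignments <- function(xy) {
  nv <- nrow(xy)
  half <- floor(nv / 2)
  s1 <- colMeans(xy[seq_len(half), , drop = FALSE])
  s2 <- colMeans(xy[(half + 1):nv, , drop = FALSE])
  if (sum((s1 - s2)^2) < 1e-18) return(NULL)
  km <- tryCatch(
    suppressWarnings(kmeans(xy, centers = rbind(s1, s2), iter.max = 100,
                            algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km)) return(NULL)
  km$cluster
}

#' Per-sample transition weights for the two-means-clustering classifier
#'
#' Runs the sliding-window two-means clustering over the recording at the
#' native rate and at each downsampled rate, and aggregates, per native
#' sample, the mean transition weight over all windows and rate variants
#' covering it. Within one clustered window, each sample at which the
#' cluster assignment switches receives weight `1 / (number of switches in
#' that window)`; windows covering a sample without switching there
#' contribute zero. Switches found in downsampled data are spread over the
#' native samples of the corresponding block.
#'
#' @param rec A `gaze_recording` in degrees.
#' @param params An [i2mc_params()] object.
#' @return A tibble with columns `time_ms`, `weight` (`NA` where no window
#'   covered the sample) and `n_windows`, with the transition cutoff in
#'   attribute `cutoff`.
#' @export
i2mc_transition_weights <- function(rec, params = i2mc_params()) {
  assert_degrees(rec)
  n <- nrow(rec)
  t <- rec$time_ms
  num <- numeric(n)
  den <- numeric(n)
  any_clustered <- FALSE

  starts <- seq(t[1], t[n] - params$window_ms, by = params$step_ms)
  if (length(starts) == 0) starts <- t[1]

  variants <- c(list(list(k = 1L, rec = rec)),
                lapply(params$downsample_factors, function(k) {
                  list(k = as.integer(k), rec = downsample_by_factor(rec, k))
                }))

  for (va in variants) {
    k <- va$k
    rv <- va$rec
    tv <- rv$time_ms
    nv_tot <- nrow(rv)
    xy_all <- cbind(rv$x, rv$y)
    validv <- rv$valid
    j_lo <- findInterval(starts - 1e-9, tv) + 1L
    j_hi <- findInterval(starts + params$window_ms - 1e-9, tv)
    for (w in seq_along(starts)) {
      a <- j_lo[w]; b <- j_hi[w]
      if (b - a + 1L < 2L) next
      win <- a:b
      ok <- validv[win]
      nv <- sum(ok)
      if (nv < 4L || nv / length(win) < params$min_valid_prop_window) next
      # native index range covered by this window's blocks
      n0 <- (a - 1L) * k + 1L
      n1 <- min(n, b * k)
      den[n0:n1] <- den[n0:n1] + 1
      cl <- two_means_assignments(xy_all[win[ok], , drop = FALSE])
      any_clustered <- TRUE
      if (is.null(cl)) next
      switch_pos <- which(diff(cl) != 0) + 1L   # position among valid samples
      if (length(switch_pos) == 0) next
      wgt <- 1 / length(switch_pos)
      sw_j <- win[ok][switch_pos]               # variant sample index
      # a switch found in downsampled data is located at the first native
      # sample of the corresponding block
      sw_native <- pmin(n, (sw_j - 1L) * k + 1L)
      num[sw_native] <- num[sw_native] + wgt
    }
  }
  if (!any_clustered) {
    stop_input("insufficient data: no window held enough valid samples to cluster")
  }
  weight <- ifelse(den > 0, num / den, NA_real_)
  mu <- mean(weight, na.rm = TRUE)
  sdev <- sd(weight, na.rm = TRUE)
  if (is.na(sdev)) sdev <- 0
  out <- tibble::tibble(time_ms = t, weight = weight, n_windows = den)
  attr(out, "cutoff") <- mu + params$weight_cutoff_sd * sdev
  out
}

#' Classify fixations by two-means clustering (I2MC)
#'
#' Computes per-sample transition weights with [i2mc_transition_weights()],
#' marks samples whose weight exceeds `mean + weight_cutoff_sd * sd` of the
#' weights as transitions, and takes the maximal intervals between
#' transition samples as fixation candidates. Candidates shorter than
#' `min_fixation_ms` or failing the missing-proportion rule are dropped, and
#' the survivors are merged under `merge_dist_deg` / `merge_gap_ms`. The
#' intervals between the final fixations are reported as saccades.
#'
#' @param rec A `gaze_recording` in degrees; the clustering window must span
#'   at least 4 samples at the coarsest downsampled rate.
#' @param params An [i2mc_params()] object.
#' @return An `event_set`.
#' @export
classify_i2mc <- function(rec, params = i2mc_params()) {
  assert_degrees(rec)
  wts <- i2mc_transition_weights(rec, params)
  cutoff <- attr(wts, "cutoff")
  transition <- !is.na(wts$weight) & wts$weight > cutoff

  spans <- run_spans(transition)
  fs <- spans[!spans$value, c("i0", "i1")]
  fs$kind <- rep("fixation", nrow(fs))
  events <- build_event_set(rec, fs, algorithm = "i2mc",
                            params = unclass(params))
  # merge before the duration filter: fragments cut by scattered transition
  # samples re-join their fixation instead of being discarded
  events <- merge_adjacent_fixations(events, rec = rec,
                                     max_dist_deg = params$merge_dist_deg,
                                     max_gap_ms = params$merge_gap_ms)
  keep <- events$duration_ms >= params$min_fixation_ms &
    events$prop_missing <= params$missing_samples_threshold
  events <- keep_event_attrs(events[keep, ], events)
  # report inter-fixation intervals as saccades for a uniform event surface
  fx <- events[events$kind == "fixation", ]
  if (nrow(fx) >= 2) {
    idx_of_time <- function(tt) which(rec$time_ms == tt)[1]
    sac_spans <- tibble::tibble(
      i0 = vapply(fx$offset_ms[-nrow(fx)], idx_of_time, integer(1)),
      i1 = vapply(fx$onset_ms[-1], idx_of_time, integer(1)),
      kind = "saccade")
    sac <- build_event_set(rec, sac_spans, algorithm = "i2mc",
                           params = unclass(params))
    events <- new_event_set(dplyr::bind_rows(tibble::as_tibble(events),
                                             tibble::as_tibble(sac)),
                            algorithm = "i2mc", params = unclass(params),
                            unit = gaze_unit(rec))
  }
  events
}
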