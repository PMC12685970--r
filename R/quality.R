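# Data-quality metrics and cross-algorithm agreement statistics.

#' Proportion of data loss in a recording
#'
#' The proportion of samples without a valid gaze coordinate. Samples that
#' were recovered by gap interpolation still count as lost: data loss is a
#' property of the recorded data, not of the pre-processed copy.
#'
#' @param rec A `gaze_recording`.
#' @return A proportion in `[0, 1]`.
#' @export
proportion_data_loss <- function(rec) {
  assert_recording(rec)
  if (nrow(rec) == 0) stop_input("Cannot compute data loss on an empty recording.")
  mean(missing_flags(rec))
}

#' Sample-to-sample RMS precision
#'
#' Imprecision is the variability of consecutive gaze position measurements
#' in the absence of eye movements, measured as the root-mean-square of the
#' Euclidean displacements between consecutive valid samples. Lower values
#' mean higher precision. For i.i.d. isotropic Gaussian position noise with
#' per-axis standard deviation `s`, the expected RMSD is `2 s`.
#'
#' @param rec A `gaze_recording`.
#' @param span Optional time interval `c(start_ms, end_ms)` restricting the
#'   computation.
#' @return RMS sample-to-sample distance in the recording's unit, or `NA`
#'   (with a warning) if no consecutive valid pair exists.
#' @export
rmsd_precision <- function(rec, span = NULL) {
  assert_recording(rec)
  idx <- seq_len(nrow(rec))
  if (!is.null(span)) {
    idx <- which(rec$time_ms >= span[1] & rec$time_ms <= span[2])
  }
  if (length(idx) < 2) {
    warn("No consecutive valid sample pair in span; RMSD undefined.")
    return(NA_real_)
  }
  x <- rec$x[idx]; y <- rec$y[idx]; ok <- rec$valid[idx]
  pair_ok <- ok[-1] & ok[-length(ok)]
  if (!any(pair_ok)) {
    warn("No consecutive valid sample pair in span; RMSD undefined.")
    return(NA_real_)
  }
  d2 <- (diff(x)^2 + diff(y)^2)[pair_ok]
  sqrt(mean(d2))
}

#' Relative timing offset/deviation between two event streams
#'
#' Matches each fixation in `a` (chronologically) to the first unused
#' fixation in `b` whose onset is at least `a`'s onset minus `margin_ms` and
#' whose offset is at most `a`'s offset plus `margin_ms` — i.e. the first
#' comparison fixation lying within the reference fixation interval, with a
#' margin. Matching is one-to-one: a comparison fixation is consumed by its
#' match, so one long fixation cannot match many. The relative timing
#' offset (RTO) is the mean of the matched onset (offset) differences and
#' the relative timing deviation (RTD) their standard deviation (n - 1
#' denominator; `NA` when fewer than two matches). Differences are signed as
#' comparison minus reference, so a positive onset RTO means `b` starts
#' later than `a`.
#'
#' @param a Reference `event_set`.
#' @param b Comparison `event_set`.
#' @param margin_ms Matching margin, ms.
#' @return A one-row tibble of class `gaze_comparison` with columns
#'   `rto_onset_ms`, `rtd_onset_ms`, `rto_offset_ms`, `rtd_offset_ms`,
#'   `n_matched`, `n_unmatched_a`, `n_unmatched_b`, `margin_ms`.
#' @export
compare_event_streams <- function(a, b, margin_ms = 15) {
  assert_event_set(a); assert_event_set(b)
  fa <- tibble::as_tibble(a[a$kind == "fixation", ])
  fb <- tibble::as_tibble(b[b$kind == "fixation", ])
  fa <- fa[order(fa$onset_ms), ]
  fb <- fb[order(fb$onset_ms), ]
  used <- rep(FALSE, nrow(fb))
  d_on <- numeric(0); d_off <- numeric(0)
  for (i in seq_len(nrow(fa))) {
    cand <- which(!used &
                    fb$onset_ms >= fa$onset_ms[i] - margin_ms &
                    fb$offset_ms <= fa$offset_ms[i] + margin_ms)
    if (length(cand) > 0) {
      j <- cand[1]
      used[j] <- TRUE
      d_on <- c(d_on, fb$onset_ms[j] - fa$onset_ms[i])
      d_off <- c(d_off, fb$offset_ms[j] - fa$offset_ms[i])
    }
  }
  n <- length(d_on)
  out <- tibble::tibble(
    rto_onset_ms = if (n > 0) mean(d_on) else NA_real_,
    rtd_onset_ms = if (n > 1) sd(d_on) else NA_real_,
    rto_offset_ms = if (n > 0) mean(d_off) else NA_real_,
    rtd_offset_ms = if (n > 1) sd(d_off) else NA_real_,
    n_matched = n,
    n_unmatched_a = nrow(fa) - n,
    n_unmatched_b = nrow(fb) - n,
    margin_ms = margin_ms)
  class(out) <- c("gaze_comparison", class(out))
  out
}

#' Descriptive fixation statistics per classification algorithm
#'
#' Summarizes one or several event sets into the descriptive quantities used
#' to compare classifiers: fixation count, mean and SD of fixation duration,
#' mean within-fixation RMSD, mean missing proportion and total fixation
#' time.
#'
#' @param sets An `event_set` or a list of them.
#' @param rec Optional source recording (reserved; statistics come from the
#'   event tables).
#' @return A tibble of class `algorithm_summary`, one row per algorithm.
#' @export
summarize_algorithms <- function(sets, rec = NULL) {
  if (inherits(sets, "event_set") || (is.data.frame(sets))) sets <- list(sets)
  all_ev <- dplyr::bind_rows(lapply(sets, tibble::as_tibble))
  fx <- all_ev[all_ev$kind == "fixation", ]
  out <- fx |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      n_fixations = dplyr::n(),
      mean_duration_ms = mean(.data$duration_ms),
      sd_duration_ms = sd(.data$duration_ms),
      mean_rmsd_deg = mean(.data$rmsd_deg, na.rm = TRUE),
      mean_prop_missing = mean(.data$prop_missing, na.rm = TRUE),
      total_fixation_time_ms = sum(.data$duration_ms),
      .groups = "drop") |>
    dplyr::rename(algorithm = "algorithm")
  # algorithms whose sets held no fixations still get a (flagged) row
  algs <- unique(unlist(lapply(sets, function(s) unique(s$algorithm))))
  algs <- algs[!is.na(algs)]
  missing_algs <- setdiff(algs, out$algorithm)
  if (length(missing_algs) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      algorithm = missing_algs, n_fixations = 0L,
      mean_duration_ms = NA_real_, sd_duration_ms = NA_real_,
      mean_rmsd_deg = NA_real_, mean_prop_missing = NA_real_,
      total_fixation_time_ms = 0))
  }
  class(out) <- c("algorithm_summary", class(out))
  out
}

#' Fixation-recovery F1 against ground truth
#'
#' Benchmarks a classifier against simulator ground truth. Detected and true
#' fixations are paired greedily by decreasing temporal overlap, one-to-one;
#' a pair counts as a true positive when the overlap covers at least
#' `min_overlap` of the shorter of the two events. F1 is the harmonic mean
#' of precision (matched / detected) and recall (matched / true).
#'
#' @param detected An `event_set` (or fixation table).
#' @param truth A ground-truth event table with `kind`, `onset_ms`,
#'   `offset_ms` (see [simulate_gaze()]).
#' @param min_overlap Minimum overlap fraction of the shorter event.
#' @return A one-row tibble with `precision`, `recall`, `f1`, `n_matched`.
#' @export
event_recovery_f1 <- function(detected, truth, min_overlap = 0.5) {
  fd <- tibble::as_tibble(detected)
  fd <- fd[fd$kind == "fixation", ]
  ft <- tibble::as_tibble(truth)
  ft <- ft[ft$kind == "fixation", ]
  nd <- nrow(fd); nt <- nrow(ft)
  if (nd == 0 || nt == 0) {
    return(tibble::tibble(precision = 0, recall = 0, f1 = 0, n_matched = 0L))
  }
  ov <- outer(seq_len(nd), seq_len(nt), Vectorize(function(i, j) {
    lo <- max(fd$onset_ms[i], ft$onset_ms[j])
    hi <- min(fd$offset_ms[i], ft$offset_ms[j])
    max(0, hi - lo)
  }))
  shorter <- outer(fd$offset_ms - fd$onset_ms, ft$offset_ms - ft$onset_ms, pmin)
  frac <- ifelse(shorter > 0, ov / shorter, 0)
  matched <- 0L
  while (TRUE) {
    best <- which(frac == max(frac), arr.ind = TRUE)[1, ]
    if (frac[best[1], best[2]] < min_overlap) break
    matched <- matched + 1L
    frac[best[1], ] <- -1
    frac[, best[2]] <- -1
    if (all(frac < min_overlap)) break
  }
  precision <- matched / nd
  recall <- matched / nt
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 n_matched = matched)
}
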