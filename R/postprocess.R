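# Post-classification event rules: merge fixations that are close in space
# and time, trim fixation edges that may belong to saccades, and discard
# unlikely events.

# Recompute a fixation row over the sample span [onset, offset] of `rec`,
# preserving the additive constituent-sample time in `sample_time_ms`.
recompute_fixation <- function(rec, onset_ms, offset_ms, sample_time_ms,
                               algorithm, dt_med = NULL) {
  idx <- which(rec$time_ms >= onset_ms & rec$time_ms <= offset_ms)
  row <- event_row(rec, idx[1], idx[length(idx)], "fixation",
                   dt_med = dt_med)
  row$onset_ms <- onset_ms
  row$offset_ms <- offset_ms
  row$duration_ms <- offset_ms - onset_ms
  row$sample_time_ms <- sample_time_ms
  row$algorithm <- algorithm
  row
}

#' Merge fixations that are close in space and time
#'
#' Repeatedly replaces any two consecutive fixations whose centroid distance
#' is at most `max_dist_deg` and whose inter-event gap is at most
#' `max_gap_ms` by one fixation spanning the first onset to the second
#' offset. The scan is chronological with an immediate re-test after each
#' merge, so chains of short fixations collapse in one pass (each test is
#' against the running merged centroid). The merged centroid is the
#' duration-weighted mean of the constituents' centroids; with `rec`
#' supplied, RMSD and the missing proportion are recomputed from the samples
#' of the merged span (gap samples included), otherwise they are
#' duration-weighted combinations. The merged span absorbs the gap, so
#' `duration_ms` may grow, while `sample_time_ms` stays the sum of the
#' constituents' sample time — the two duration notions are deliberately
#' kept distinct. Saccades wholly inside a merged span are removed.
#'
#' @param events An `event_set`.
#' @param rec Optional source `gaze_recording` for exact recomputation of
#'   per-event sample statistics.
#' @param max_dist_deg Maximum centroid distance, deg.
#' @param max_gap_ms Maximum inter-fixation gap, ms.
#' @return An `event_set`.
#' @export
merge_adjacent_fixations <- function(events, rec = NULL, max_dist_deg = 0.7,
                                     max_gap_ms = 50) {
  assert_event_set(events)
  if (max_dist_deg < 0 || max_gap_ms < 0) {
    stop_param("Merge thresholds must be >= 0.")
  }
  fx <- tibble::as_tibble(events[events$kind == "fixation", ])
  other <- tibble::as_tibble(events[events$kind != "fixation", ])
  if (nrow(fx) >= 2) {
    fx <- fx[order(fx$onset_ms), ]
    dt_med <- if (!is.null(rec)) sample_interval_ms(rec) else NULL
    i <- 1L
    while (i < nrow(fx)) {
      gap <- fx$onset_ms[i + 1L] - fx$offset_ms[i]
      dist <- sqrt((fx$x[i + 1L] - fx$x[i])^2 + (fx$y[i + 1L] - fx$y[i])^2)
      if (!is.na(dist) && dist <= max_dist_deg && gap <= max_gap_ms) {
        w <- c(fx$duration_ms[i], fx$duration_ms[i + 1L])
        if (all(w == 0)) w <- c(1, 1)
        cx <- weighted.mean(fx$x[c(i, i + 1L)], w)
        cy <- weighted.mean(fx$y[c(i, i + 1L)], w)
        st <- fx$sample_time_ms[i] + fx$sample_time_ms[i + 1L]
        if (!is.null(rec)) {
          row <- recompute_fixation(rec, fx$onset_ms[i], fx$offset_ms[i + 1L],
                                    st, fx$algorithm[i], dt_med)
        } else {
          row <- fx[i, ]
          row$offset_ms <- fx$offset_ms[i + 1L]
          row$duration_ms <- row$offset_ms - row$onset_ms
          row$rmsd_deg <- sqrt(weighted.mean(c(fx$rmsd_deg[i]^2,
                                               fx$rmsd_deg[i + 1L]^2), w))
          row$prop_missing <- weighted.mean(fx$prop_missing[c(i, i + 1L)], w)
          row$n_samples <- fx$n_samples[i] + fx$n_samples[i + 1L]
          row$sample_time_ms <- st
        }
        row$x <- cx
        row$y <- cy
        fx <- dplyr::bind_rows(
          if (i > 1L) fx[seq_len(i - 1L), ],
          row,
          if (i + 1L < nrow(fx)) fx[(i + 2L):nrow(fx), ])
        # re-test the merged fixation against its new right neighbour
      } else {
        i <- i + 1L
      }
    }
    if (nrow(other) > 0 && nrow(fx) > 0) {
      inside <- vapply(seq_len(nrow(other)), function(k) {
        any(other$onset_ms[k] >= fx$onset_ms &
              other$offset_ms[k] <= fx$offset_ms)
      }, logical(1))
      other <- other[!inside, ]
    }
  }
  new_event_set(dplyr::bind_rows(fx, other),
                algorithm = unique(events$algorithm),
                params = attr(events, "params"),
                unit = attr(events, "unit") %||% "deg")
}

#' Trim fixation edges that may belong to saccades
#'
#' Advances every fixation's onset and recedes its offset by `trim_ms`,
#' dropping fixations whose trimmed duration is not positive. Centroid,
#' RMSD and missing proportion are recomputed on the trimmed sample span
#' when `rec` is supplied. Saccades are untouched.
#'
#' @param events An `event_set`.
#' @param rec Optional source `gaze_recording` for recomputation.
#' @param trim_ms Duration removed from each fixation edge, ms (>= 0).
#' @return An `event_set`.
#' @export
trim_fixations <- function(events, rec = NULL, trim_ms = 0) {
  assert_event_set(events)
  if (trim_ms < 0) stop_param("trim_ms must be >= 0.")
  if (trim_ms == 0) return(events)
  fx <- tibble::as_tibble(events[events$kind == "fixation", ])
  other <- tibble::as_tibble(events[events$kind != "fixation", ])
  if (nrow(fx) > 0) {
    fx$onset_ms <- fx$onset_ms + trim_ms
    fx$offset_ms <- fx$offset_ms - trim_ms
    fx <- fx[fx$offset_ms - fx$onset_ms > 0, ]
    if (!is.null(rec) && nrow(fx) > 0) {
      dt_med <- sample_interval_ms(rec)
      fx <- dplyr::bind_rows(purrr::pmap(
        list(fx$onset_ms, fx$offset_ms, fx$algorithm),
        function(on, off, alg) {
          idx <- which(rec$time_ms >= on & rec$time_ms <= off)
          st <- length(idx) * dt_med
          recompute_fixation(rec, on, off, st, alg, dt_med)
        }))
    } else if (nrow(fx) > 0) {
      fx$duration_ms <- fx$offset_ms - fx$onset_ms
    }
  }
  new_event_set(dplyr::bind_rows(fx, other),
                algorithm = unique(events$algorithm),
                params = attr(events, "params"),
                unit = attr(events, "unit") %||% "deg")
}

#' Discard unlikely fixations and saccades
#'
#' Removes fixations shorter than `min_duration_ms` or with an
#' originally-missing sample proportion above `max_prop_missing`, and
#' optionally saccades shorter than `min_saccade_ms` or smaller than
#' `min_saccade_amplitude_deg` (small "saccades" in noisy data are usually
#' artefacts).
#'
#' @param events An `event_set`.
#' @param min_duration_ms Minimum fixation duration to keep.
#' @param max_prop_missing Maximum fixation missing proportion to keep.
#' @param min_saccade_ms,min_saccade_amplitude_deg Optional saccade bounds;
#'   `NULL` keeps all saccades.
#' @return An `event_set`.
#' @export
drop_fixations <- function(events, min_duration_ms = 60, max_prop_missing = 1,
                           min_saccade_ms = NULL,
                           min_saccade_amplitude_deg = NULL) {
  assert_event_set(events)
  keep <- rep(TRUE, nrow(events))
  is_fix <- events$kind == "fixation"
  keep[is_fix] <- events$duration_ms[is_fix] >= min_duration_ms &
    (is.na(events$prop_missing[is_fix]) |
       events$prop_missing[is_fix] <= max_prop_missing)
  is_sac <- events$kind == "saccade"
  if (!is.null(min_saccade_ms)) {
    keep[is_sac] <- keep[is_sac] & events$duration_ms[is_sac] >= min_saccade_ms
  }
  if (!is.null(min_saccade_amplitude_deg)) {
    keep[is_sac] <- keep[is_sac] &
      (is.na(events$amplitude_deg[is_sac]) |
         events$amplitude_deg[is_sac] >= min_saccade_amplitude_deg)
  }
  keep_event_attrs(events[keep, ], events)
}
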