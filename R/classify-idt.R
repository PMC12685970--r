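# Identification by dispersion threshold (I-DT): fixations are runs of
# samples staying within a fixed radius of their running centroid.

#' Parameters for the dispersion-threshold classifier
#'
#' @param dispersion_threshold_deg Maximum Euclidean distance of an incoming
#'   sample from the running centroid of the candidate fixation, deg. A value
#'   of 1 degree is the common recommendation (the fovea covers about
#'   2 degrees).
#' @param min_fixation_ms Minimum fixation duration.
#' @param missing_samples_threshold Maximum proportion of originally-missing
#'   constituent samples for a fixation to be kept (invalid samples inside a
#'   candidate are tolerated up to this proportion).
#'
#' @return A list of class `idt_params`.
#' @export
idt_params <- function(dispersion_threshold_deg = 1.0, min_fixation_ms = 60,
                       missing_samples_threshold = 0.5) {
  if (dispersion_threshold_deg <= 0) stop_param("dispersion_threshold_deg must be > 0")
  if (min_fixation_ms < 0) stop_param("min_fixation_ms must be >= 0")
  structure(list(dispersion_threshold_deg = dispersion_threshold_deg,
                 min_fixation_ms = min_fixation_ms,
                 missing_samples_threshold = missing_samples_threshold),
            class = "idt_params")
}

#' Classify fixations by dispersion threshold (I-DT)
#'
#' Greedy left-to-right scan: the candidate fixation is extended sample by
#' sample as long as every incoming valid sample lies within
#' `dispersion_threshold_deg` of the running centroid of the valid samples
#' included so far. On a violation the candidate is emitted as a fixation if
#' it lasts at least `min_fixation_ms` (and passes the missing-proportion
#' rule), and the scan restarts at the violating sample. Invalid samples
#' inside a candidate are tolerated; they do not move the centroid. The
#' intervals between consecutive fixations are reported as saccades without
#' velocity metrics (dispersion algorithms do not measure velocity); they
#' exist so that latency-based analyses work uniformly across classifiers.
#'
#' @param rec A `gaze_recording` in degrees.
#' @param params An [idt_params()] object.
#' @return An `event_set`.
#' @export
classify_idt <- function(rec, params = idt_params()) {
  assert_degrees(rec)
  n <- nrow(rec)
  t <- rec$time_ms; x <- rec$x; y <- rec$y; valid <- rec$valid

  fix_spans <- list()
  cand_start <- NA_integer_
  cand_last <- NA_integer_   # last sample included (valid or not)
  sx <- 0; sy <- 0; cnt <- 0L  # running sums over valid included samples

  emit <- function(i0, i1) {
    if (is.na(i0) || cnt == 0L) return(invisible(NULL))
    if (t[i1] - t[i0] >= params$min_fixation_ms) {
      fix_spans[[length(fix_spans) + 1L]] <<- c(i0, i1)
    }
    invisible(NULL)
  }

  i <- 1L
  while (i <= n) {
    if (!valid[i]) {
      if (!is.na(cand_start)) cand_last <- i
      i <- i + 1L
      next
    }
    if (is.na(cand_start)) {
      cand_start <- i; cand_last <- i
      sx <- x[i]; sy <- y[i]; cnt <- 1L
      i <- i + 1L
      next
    }
    d <- sqrt((x[i] - sx / cnt)^2 + (y[i] - sy / cnt)^2)
    if (d <= params$dispersion_threshold_deg) {
      sx <- sx + x[i]; sy <- sy + y[i]; cnt <- cnt + 1L
      cand_last <- i
      i <- i + 1L
    } else {
      emit(cand_start, cand_last)
      cand_start <- i; cand_last <- i
      sx <- x[i]; sy <- y[i]; cnt <- 1L
      i <- i + 1L
    }
  }
  emit(cand_start, cand_last)

  fs <- if (length(fix_spans) == 0) {
    tibble::tibble(i0 = integer(), i1 = integer())
  } else {
    m <- do.call(rbind, fix_spans)
    tibble::tibble(i0 = m[, 1], i1 = m[, 2])
  }
  fs$kind <- rep("fixation", nrow(fs))
  spans <- dplyr::bind_rows(fs, interfixation_saccade_spans(fs))
  events <- build_event_set(rec, spans, algorithm = "idt",
                            params = unclass(params))
  keep <- events$kind == "saccade" |
    events$prop_missing <= params$missing_samples_threshold
  keep_event_attrs(events[keep, ], events)
}
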