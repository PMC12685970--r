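# broom-style tidiers and autoplot methods for the package's result types.

#' Tidy an event set
#'
#' Returns the event table as a plain tibble (one row per event), dropping
#' the class and parameter attributes.
#'
#' @param x An `event_set`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy event_set
#' @export
tidy.event_set <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "event_set")
  attr(out, "params") <- NULL
  out
}

#' One-row summary of an event set
#'
#' @param x An `event_set`.
#' @param ... Unused.
#' @return A one-row tibble with fixation/saccade counts, mean and total
#'   fixation duration, mean within-fixation RMSD and mean missing
#'   proportion.
#' @method glance event_set
#' @export
glance.event_set <- function(x, ...) {
  fx <- x[x$kind == "fixation", ]
  tibble::tibble(
    algorithm = paste(unique(x$algorithm), collapse = ","),
    n_fixations = nrow(fx),
    n_saccades = sum(x$kind == "saccade"),
    mean_fixation_ms = if (nrow(fx) > 0) mean(fx$duration_ms) else NA_real_,
    total_fixation_ms = sum(fx$duration_ms),
    mean_rmsd_deg = if (nrow(fx) > 0) mean(fx$rmsd_deg, na.rm = TRUE) else NA_real_,
    mean_prop_missing = if (nrow(fx) > 0) mean(fx$prop_missing, na.rm = TRUE) else NA_real_)
}

#' Tidy an event-stream comparison
#'
#' @param x A `gaze_comparison` from [compare_event_streams()].
#' @param ... Unused.
#' @return A long tibble with `statistic` and `value` columns.
#' @method tidy gaze_comparison
#' @export
tidy.gaze_comparison <- function(x, ...) {
  df <- tibble::as_tibble(x)
  class(df) <- setdiff(class(df), "gaze_comparison")
  tidyr::pivot_longer(df, cols = dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @method glance gaze_comparison
#' @export
glance.gaze_comparison <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "gaze_comparison")
  out
}

#' Autoplot methods
#'
#' `autoplot()` gives the natural default view of each result type: the
#' x-coordinate time series for a recording, the velocity trace for a
#' `velocity_trace`, and the quality panel for an `algorithm_summary`.
#'
#' @param object The object to plot.
#' @param ... Passed to the underlying `plot_*()` function.
#' @return A ggplot.
#' @name autoplot-gazekit
NULL

#' @rdname autoplot-gazekit
#' @method autoplot gaze_recording
#' @export
autoplot.gaze_recording <- function(object, ...) plot_timeseries(object, ...)

#' @rdname autoplot-gazekit
#' @method autoplot velocity_trace
#' @export
autoplot.velocity_trace <- function(object, ...) plot_velocity(object, ...)

#' @rdname autoplot-gazekit
#' @method autoplot algorithm_summary
#' @export
autoplot.algorithm_summary <- function(object, ...) plot_algorithm_quality(object, ...)
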