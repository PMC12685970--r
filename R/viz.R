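# Visualization surface: QC and publication figures for recordings,
# velocity traces, event sets and AOI overlays. Every plot function builds a
# ggplot; when `out` is given the plot is rendered to that file with a fixed
# raster device and the path returned, so renders are reproducible.

render_plot <- function(p, out, width = 7, height = 5) {
  if (is.null(out)) return(p)
  grDevices::png(out, width = width, height = height, units = "in", res = 150)
  print(p)
  grDevices::dev.off()
  invisible(out)
}

clip_span <- function(df, span, col = "time_ms") {
  if (is.null(span)) return(df)
  if (span[2] <= span[1]) stop_input("Plot span must have positive length.")
  df[df[[col]] >= span[1] & df[[col]] <= span[2], ]
}

maybe_background <- function(p, background) {
  if (is.null(background)) return(p)
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_config("Reading a background image requires the 'png' package.")
  }
  img <- png::readPNG(background)
  h <- dim(img)[1]; w <- dim(img)[2]
  # screen convention: origin top-left, y grows downward
  p + ggplot2::annotation_raster(img, xmin = 0, xmax = w, ymin = h, ymax = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = NULL, expand = FALSE)
}

#' Plot samples and fixation centroids in 2D space
#'
#' Raw samples are drawn as small points and each event set's fixation
#' centroids as markers scaled by fixation duration, one color per set, so
#' the spatial output of up to six classifiers can be compared on one
#' stimulus.
#'
#' @param rec A `gaze_recording`.
#' @param sets An `event_set` or a named list of up to six.
#' @param out Optional PNG output path; when given, the rendered file path
#'   is returned instead of the plot object.
#' @param background Optional PNG stimulus image (pixel-unit data only).
#' @return A ggplot, or `out` invisibly.
#' @export
plot_fixations_2d <- function(rec, sets = list(), out = NULL,
                              background = NULL) {
  assert_recording(rec)
  if (inherits(sets, "event_set") || is.data.frame(sets)) sets <- list(sets)
  if (length(sets) > 6) stop_input("At most six event sets can be overlaid.")
  if (!is.null(background) && !identical(gaze_unit(rec), "px")) {
    stop_unit("A background image requires pixel-unit data.")
  }
  samples <- tibble::as_tibble(rec)[rec$valid, c("x", "y")]
  fx <- dplyr::bind_rows(lapply(seq_along(sets), function(k) {
    s <- tibble::as_tibble(sets[[k]])
    s <- s[s$kind == "fixation", ]
    s$set <- names(sets)[k] %||% unique(s$algorithm)[1] %||% paste0("set", k)
    s
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = samples, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 0.3, alpha = 0.4, colour = "grey40")
  if (nrow(fx) > 0) {
    p <- p + ggplot2::geom_point(
      data = fx,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$duration_ms,
                   colour = .data$set),
      alpha = 0.7)
  }
  p <- p +
    ggplot2::scale_size_continuous(name = "duration (ms)") +
    ggplot2::labs(x = paste0("x (", gaze_unit(rec), ")"),
                  y = paste0("y (", gaze_unit(rec), ")"),
                  colour = "algorithm") +
    ggplot2::theme_minimal()
  p <- maybe_background(p, background)
  render_plot(p, out)
}

#' Plot gaze coordinates against time
#'
#' Draws one coordinate axis of up to two recordings (e.g. raw vs
#' pre-processed) as lines, with gaps where samples are invalid, and
#' overlays per-fixation coordinates as horizontal step segments for any
#' supplied event sets.
#'
#' @param rec A `gaze_recording`.
#' @param rec_b Optional second recording to overlay.
#' @param sets Optional `event_set` or list of them.
#' @param axis `"x"` or `"y"`.
#' @param span Optional time interval `c(start_ms, end_ms)`.
#' @param out Optional PNG output path.
#' @return A ggplot, or `out` invisibly.
#' @export
plot_timeseries <- function(rec, rec_b = NULL, sets = NULL, axis = c("x", "y"),
                            span = NULL, out = NULL) {
  assert_recording(rec)
  axis <- match.arg(axis)
  series <- list(a = rec)
  if (!is.null(rec_b)) series$b <- rec_b
  df <- dplyr::bind_rows(lapply(names(series), function(nm) {
    r <- series[[nm]]
    tibble::tibble(time_ms = r$time_ms,
                   value = ifelse(r$valid, r[[axis]], NA_real_),
                   series = nm)
  }))
  df <- clip_span(df, span)
  if (nrow(df) == 0) stop_input("No samples in the requested span.")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value,
                                        colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (ms)", y = paste0(axis, " (", gaze_unit(rec), ")"),
                  colour = "series") +
    ggplot2::theme_minimal()
  if (!is.null(sets)) {
    if (inherits(sets, "event_set") || is.data.frame(sets)) sets <- list(sets)
    fx <- dplyr::bind_rows(lapply(sets, function(s) {
      s <- tibble::as_tibble(s); s[s$kind == "fixation", ]
    }))
    if (!is.null(span)) {
      fx <- fx[fx$offset_ms >= span[1] & fx$onset_ms <= span[2], ]
    }
    if (nrow(fx) > 0) {
      fx$value <- fx[[axis]]
      p <- p + ggplot2::geom_segment(
        data = fx,
        ggplot2::aes(x = .data$onset_ms, xend = .data$offset_ms,
                     y = .data$value, yend = .data$value,
                     linetype = .data$algorithm),
        inherit.aes = FALSE, linewidth = 1)
    }
  }
  render_plot(p, out)
}

#' Plot sample-to-sample velocity
#'
#' The standard view for choosing a saccade velocity threshold: velocity
#' against time with an optional dashed horizontal line at a proposed
#' threshold.
#'
#' @param vel A `velocity_trace`.
#' @param threshold_dps Optional threshold line, deg/s.
#' @param span Optional time interval.
#' @param out Optional PNG output path.
#' @return A ggplot, or `out` invisibly.
#' @export
plot_velocity <- function(vel, threshold_dps = NULL, span = NULL, out = NULL) {
  df <- clip_span(tibble::as_tibble(vel), span)
  if (nrow(df) == 0) stop_input("No samples in the requested span.")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms,
                                        y = .data$velocity_dps)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "time (ms)", y = "velocity (deg/s)") +
    ggplot2::theme_minimal()
  if (!is.null(threshold_dps)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_dps,
                                 linetype = "dashed")
  }
  render_plot(p, out)
}

#' Overlay the velocity profiles of classified saccades
#'
#' One velocity-versus-time-from-onset curve per saccade; physiologically
#' plausible saccades show a single unimodal peak.
#'
#' @param rec A `gaze_recording` in degrees.
#' @param events An `event_set` containing saccades.
#' @param out Optional PNG output path.
#' @return A ggplot, or `out` invisibly.
#' @export
plot_saccade_profiles <- function(rec, events, out = NULL) {
  assert_degrees(rec)
  vel <- compute_velocity(rec)
  sac <- tibble::as_tibble(events)
  sac <- sac[sac$kind == "saccade", ]
  df <- dplyr::bind_rows(lapply(seq_len(nrow(sac)), function(k) {
    idx <- which(vel$time_ms >= sac$onset_ms[k] & vel$time_ms <= sac$offset_ms[k])
    tibble::tibble(rel_ms = vel$time_ms[idx] - sac$onset_ms[k],
                   velocity_dps = vel$velocity_dps[idx],
                   saccade = factor(k))
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_ms,
                                        y = .data$velocity_dps,
                                        colour = .data$saccade))
  if (nrow(df) > 0) p <- p + ggplot2::geom_line(na.rm = TRUE)
  p <- p +
    ggplot2::labs(x = "time from saccade onset (ms)", y = "velocity (deg/s)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  render_plot(p, out)
}

#' Plot per-algorithm fixation quality metrics
#'
#' Bar panels of the [summarize_algorithms()] quantities, the standard way
#' to compare the data quality of fixations each classifier reports.
#'
#' @param summary An `algorithm_summary` tibble.
#' @param out Optional PNG output path.
#' @return A ggplot, or `out` invisibly.
#' @export
plot_algorithm_quality <- function(summary, out = NULL) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(summary),
    cols = c("n_fixations", "mean_duration_ms", "mean_rmsd_deg",
             "mean_prop_missing", "total_fixation_time_ms"),
    names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$algorithm,
                                          y = .data$value,
                                          fill = .data$algorithm)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none") +
    ggplot2::labs(x = NULL, y = NULL)
  render_plot(p, out, width = 8, height = 5)
}

#' Static or animated scanpath plot
#'
#' Static mode draws each participant's fixation sequence as numbered
#' markers joined by lines, colored by group. Animated mode renders a
#' deterministic sequence of PNG frames advancing in event time
#' (`frame_ms` of event time per frame) and returns the frame paths; the
#' frames can be assembled into a video/GIF with any external encoder.
#'
#' @param sets Named list of `event_set`s, one per participant.
#' @param groups Optional character vector (recycled) assigning each
#'   participant to a group.
#' @param background Optional PNG stimulus image (pixel-unit sets only).
#' @param span Optional time interval.
#' @param out Output PNG path (static) or path prefix (animated frames are
#'   written as `<out>_frame_###.png`).
#' @param animate Render animation frames instead of a static plot?
#' @param frame_ms Event time per animation frame, ms.
#' @return Static: a ggplot or `out`. Animated: character vector of frame
#'   paths.
#' @export
scanpath_plot <- function(sets, groups = NULL, background = NULL, span = NULL,
                          out = NULL, animate = FALSE, frame_ms = 500) {
  if (inherits(sets, "event_set") || is.data.frame(sets)) sets <- list(p1 = sets)
  ids <- names(sets) %||% paste0("p", seq_along(sets))
  groups <- rep_len(groups %||% "all", length(sets))
  fx <- dplyr::bind_rows(lapply(seq_along(sets), function(k) {
    s <- tibble::as_tibble(sets[[k]])
    s <- s[s$kind == "fixation", ]
    s <- s[order(s$onset_ms), ]
    if (!is.null(span)) s <- s[s$offset_ms >= span[1] & s$onset_ms <= span[2], ]
    if (nrow(s) > 0) s$order <- seq_len(nrow(s))
    s$participant <- rep(ids[k], nrow(s))
    s$group <- rep(groups[k], nrow(s))
    s
  }))
  unit <- attr(sets[[1]], "unit") %||% "deg"
  if (!is.null(background) && !identical(unit, "px")) {
    stop_unit("A background image requires pixel-unit event sets.")
  }

  base_plot <- function(dat) {
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                           colour = .data$group,
                                           group = .data$participant)) +
      ggplot2::labs(x = paste0("x (", unit, ")"), y = paste0("y (", unit, ")"),
                    colour = "group") +
      ggplot2::theme_minimal()
    if (nrow(dat) > 0) {
      p <- p + ggplot2::geom_path(alpha = 0.6) +
        ggplot2::geom_point(ggplot2::aes(size = .data$duration_ms),
                            alpha = 0.7) +
        ggplot2::geom_text(ggplot2::aes(label = .data$order), size = 3,
                           vjust = -1, show.legend = FALSE) +
        ggplot2::scale_size_continuous(name = "duration (ms)")
    }
    maybe_background(p, background)
  }

  if (!animate) {
    return(render_plot(base_plot(fx), out))
  }
  if (is.null(out)) stop_config("Animated scanpaths need an `out` path prefix.")
  t0 <- if (is.null(span)) min(fx$onset_ms) else span[1]
  t1 <- if (is.null(span)) max(fx$offset_ms) else span[2]
  times <- seq(t0 + frame_ms, t1 + frame_ms, by = frame_ms)
  prefix <- sub("\\.png$", "", out)
  paths <- character(0)
  for (k in seq_along(times)) {
    frame <- fx[fx$onset_ms <= times[k], ]
    path <- sprintf("%s_frame_%03d.png", prefix, k)
    render_plot(base_plot(frame), path)
    paths <- c(paths, path)
  }
  paths
}
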