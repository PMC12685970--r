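# Gaze recordings: the per-sample substrate of every pipeline stage.
#
# A gaze recording is a tibble with columns `time_ms`, `x`, `y`, `valid`,
# `interpolated` plus attributes `unit` ("px", "deg" or "prop"), `geometry`
# (a screen_geometry, optional) and `rate_hz` (nominal sampling rate,
# optional). Canonical internal units are degrees of visual angle for space
# and milliseconds for time; all classifiers require degrees.

#' Screen geometry for pixel/degree conversion
#'
#' Describes the physical display and the viewing position needed to convert
#' gaze coordinates between pixels and degrees of visual angle.
#'
#' @param distance_cm Viewing distance from the eye to the screen, in cm.
#' @param screen_width_cm,screen_height_cm Physical screen size, in cm.
#' @param res_x_px,res_y_px Display resolution, in pixels.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' # a 23.8-inch 16:9 monitor viewed from 65 cm
#' screen_geometry(65, 52.7, 29.6, 1920, 1080)
#' @export
screen_geometry <- function(distance_cm, screen_width_cm, screen_height_cm,
                            res_x_px, res_y_px) {
  vals <- c(distance_cm = distance_cm, screen_width_cm = screen_width_cm,
            screen_height_cm = screen_height_cm, res_x_px = res_x_px,
            res_y_px = res_y_px)
  if (length(vals) != 5 || any(!is.finite(vals)) || any(vals <= 0)) {
    stop_config("All screen geometry fields must be strictly positive finite numbers.")
  }
  structure(as.list(vals), class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf(
    "<screen_geometry> %.1f x %.1f cm, %d x %d px, viewed from %.1f cm\n",
    x$screen_width_cm, x$screen_height_cm, x$res_x_px, x$res_y_px, x$distance_cm))
  invisible(x)
}

new_gaze_recording <- function(df, unit, geometry = NULL, rate_hz = NULL) {
  out <- tibble::as_tibble(df)
  if (!"interpolated" %in% names(out)) out$interpolated <- FALSE
  out <- out[, c("time_ms", "x", "y", "valid", "interpolated")]
  attr(out, "unit") <- unit
  attr(out, "geometry") <- geometry
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("gaze_recording", class(out))
  out
}

#' Build a gaze recording from a data frame
#'
#' Tags a per-sample table of gaze coordinates with its coordinate unit and
#' (optionally) screen geometry, after validating the basic invariants:
#' strictly increasing timestamps and one validity flag per sample. Samples
#' with a non-finite coordinate are marked invalid; coordinates of invalid
#' samples are treated as undefined everywhere downstream.
#'
#' @param df Data frame with columns `time_ms`, `x`, `y` and optionally
#'   `valid` (logical, default all `TRUE`) and `interpolated` (logical,
#'   default all `FALSE`).
#' @param unit Coordinate unit: `"px"`, `"deg"` or `"prop"`
#'   (screen proportion).
#' @param geometry Optional [screen_geometry()], required later for
#'   pixel/degree conversion.
#' @param rate_hz Optional nominal sampling rate; estimated from timestamps
#'   when absent.
#'
#' @return A `gaze_recording` tibble.
#' @examples
#' as_gaze_recording(
#'   data.frame(time_ms = 0:3, x = c(1, 2, NA, 2), y = 0),
#'   unit = "deg"
#' )
#' @export
as_gaze_recording <- function(df, unit = c("deg", "px", "prop"),
                              geometry = NULL, rate_hz = NULL) {
  unit <- match.arg(unit)
  df <- tibble::as_tibble(df)
  needed <- c("time_ms", "x", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop_config(paste0("Missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(df$time_ms)) stop_input("Timestamps must be numeric.")
  if (!"valid" %in% names(df)) df$valid <- TRUE
  if (!"interpolated" %in% names(df)) df$interpolated <- FALSE
  df$valid <- as.logical(df$valid) & is.finite(df$x) & is.finite(df$y)
  df$valid[is.na(df$valid)] <- FALSE
  check_monotone_time(df$time_ms)
  if (!is.null(geometry) && !inherits(geometry, "screen_geometry")) {
    stop_config("`geometry` must be a screen_geometry object.")
  }
  new_gaze_recording(df, unit = unit, geometry = geometry, rate_hz = rate_hz)
}

check_monotone_time <- function(t) {
  if (length(t) >= 2) {
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0) {
      stop_input(sprintf(
        "Timestamps must be strictly increasing; first offending sample index: %d",
        bad[1] + 1L))
    }
  }
  invisible(TRUE)
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %d samples, unit = %s, %.1f ms span, %.1f%% valid\n",
              nrow(x), gaze_unit(x), diff(range(x$time_ms)),
              100 * mean(x$valid)))
  NextMethod()
}

#' Recording metadata accessors
#'
#' @param rec A `gaze_recording`.
#' @return `gaze_unit()` returns the coordinate unit tag, `gaze_geometry()`
#'   the attached [screen_geometry()] (or `NULL`).
#' @export
gaze_unit <- function(rec) attr(rec, "unit") %||% "deg"

#' @rdname gaze_unit
#' @export
gaze_geometry <- function(rec) attr(rec, "geometry")

assert_recording <- function(rec) {
  if (!inherits(rec, "gaze_recording")) {
    stop_input("Expected a gaze_recording (see as_gaze_recording()).")
  }
  invisible(rec)
}

assert_degrees <- function(rec) {
  assert_recording(rec)
  if (!identical(gaze_unit(rec), "deg")) {
    stop_unit(paste0("Recording must be in degrees; got unit '", gaze_unit(rec),
                     "'. Convert with pixels_to_degrees()."))
  }
  invisible(rec)
}

# Median inter-sample interval in ms; the time grid is assumed regular up to
# dropped samples, which the median ignores.
sample_interval_ms <- function(rec) {
  if (nrow(rec) < 2) return(NA_real_)
  median(diff(rec$time_ms))
}

#' Estimate the sampling rate of a recording
#'
#' Returns `1000 / median(inter-sample interval in ms)`. The median makes the
#' estimate robust to occasional dropped samples.
#'
#' @param rec A `gaze_recording` with at least two samples.
#' @return Sampling rate in Hz.
#' @examples
#' rec <- as_gaze_recording(data.frame(time_ms = 0:9, x = 0, y = 0), "deg")
#' estimate_sampling_rate(rec)  # 1000 Hz
#' @export
estimate_sampling_rate <- function(rec) {
  assert_recording(rec)
  if (nrow(rec) < 2) stop_input("Need at least 2 samples to estimate a sampling rate.")
  1000 / sample_interval_ms(rec)
}

recording_rate <- function(rec) {
  attr(rec, "rate_hz") %||% estimate_sampling_rate(rec)
}

#' Read a delimited table of gaze samples
#'
#' Reads a CSV/TSV file of per-sample gaze data into a [gaze_recording].
#' Column names in the file are mapped to the recording fields through
#' `column_map`. Rows with a non-finite coordinate, or flagged invalid by a
#' mapped validity column, become invalid samples. Timestamps are converted
#' to milliseconds and re-based so the first sample is at 0 ms.
#'
#' Binocular input is supported by mapping two coordinate pairs
#' (`x_left`/`y_left` and `x_right`/`y_right`, optionally `valid_left`/
#' `valid_right`): the two eyes are averaged where both are valid, the valid
#' eye is used where only one is, and the sample is invalid where neither is.
#'
#' @param path Path to a delimited text file.
#' @param column_map Named list mapping recording fields to file columns.
#'   Monocular: `t`, `x`, `y`, optional `valid`. Binocular: `t`, `x_left`,
#'   `y_left`, `x_right`, `y_right`, optional `valid_left`, `valid_right`.
#' @param unit Coordinate unit of the file: `"px"`, `"deg"` or `"prop"`.
#' @param geometry Optional [screen_geometry()] carried on the recording.
#' @param time_unit Unit of the timestamp column: `"ms"` (default), `"s"`
#'   or `"us"`.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.tab` use tab, everything else comma).
#'
#' @return A `gaze_recording` tibble.
#' @export
read_gaze_table <- function(path, column_map = list(t = "t", x = "x", y = "y"),
                            unit = c("px", "deg", "prop"), geometry = NULL,
                            time_unit = c("ms", "s", "us"), delim = NULL) {
  unit <- match.arg(unit)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop_io(paste0("File not found: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, comment = "#")

  pick <- function(field, required = FALSE) {
    col <- column_map[[field]]
    if (is.null(col)) {
      if (required) stop_config(paste0("column_map is missing an entry for '", field, "'"))
      return(NULL)
    }
    if (!col %in% names(raw)) {
      stop_config(sprintf("Column '%s' (mapped to '%s') not found in %s",
                          col, field, path))
    }
    raw[[col]]
  }

  t <- pick("t", required = TRUE)
  if (!is.numeric(t)) stop_input("Mapped timestamp column must be numeric.")
  t <- t * switch(time_unit, ms = 1, s = 1000, us = 1e-3)

  binocular <- any(c("x_left", "x_right") %in% names(column_map))
  if (binocular) {
    xl <- pick("x_left", required = TRUE); yl <- pick("y_left", required = TRUE)
    xr <- pick("x_right", required = TRUE); yr <- pick("y_right", required = TRUE)
    vl <- coerce_valid(pick("valid_left")) & is.finite(xl) & is.finite(yl)
    vr <- coerce_valid(pick("valid_right")) & is.finite(xr) & is.finite(yr)
    x <- ifelse(vl & vr, (xl + xr) / 2, ifelse(vl, xl, ifelse(vr, xr, NA_real_)))
    y <- ifelse(vl & vr, (yl + yr) / 2, ifelse(vl, yl, ifelse(vr, yr, NA_real_)))
    valid <- vl | vr
  } else {
    x <- as.numeric(pick("x", required = TRUE))
    y <- as.numeric(pick("y", required = TRUE))
    valid <- coerce_valid(pick("valid")) & is.finite(x) & is.finite(y)
  }

  check_monotone_time(t)
  as_gaze_recording(
    tibble::tibble(time_ms = t - t[1], x = x, y = y, valid = valid),
    unit = unit, geometry = geometry)
}

# A validity column may be logical or numeric 0/1; NULL means "all valid".
coerce_valid <- function(v) {
  if (is.null(v)) return(TRUE)
  if (is.numeric(v)) return(!is.na(v) & v != 0)
  out <- as.logical(v)
  out[is.na(out)] <- FALSE
  out
}

#' Write a gaze recording to CSV
#'
#' Writes `time_ms`, `x`, `y`, `valid`, `interpolated` with the coordinate
#' unit in a `#`-prefixed header comment.
#'
#' @param rec A `gaze_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(rec, path) {
  assert_recording(rec)
  body <- readr::format_csv(tibble::as_tibble(unclass_recording(rec)))
  out <- tryCatch(
    writeLines(c(paste0("# unit: ", gaze_unit(rec)), sub("\n$", "", body)), path),
    error = function(e) stop_io(conditionMessage(e)))
  invisible(path)
}

unclass_recording <- function(rec) {
  out <- rec
  class(out) <- setdiff(class(out), "gaze_recording")
  attr(out, "unit") <- NULL; attr(out, "geometry") <- NULL; attr(out, "rate_hz") <- NULL
  out
}

# ---- unit conversion ----------------------------------------------------

#' Convert gaze coordinates between pixels and degrees
#'
#' `pixels_to_degrees()` converts a pixel-unit recording to degrees of visual
#' angle: per axis, the offset from the screen center in cm is converted to
#' the angle it subtends at the eye (`atan(offset / distance)`), using the
#' attached [screen_geometry()]. `degrees_to_pixels()` is the exact inverse.
#' `proportion_to_pixels()` scales screen-proportion coordinates to pixels via
#' the display resolution (the single conversion path to degrees for
#' proportion data). Validity flags are never altered by unit conversion.
#'
#' The arctangent conversion is exact and monotone; it is not the small-angle
#' linear approximation, so the two differ slightly for peripheral gaze.
#'
#' @param rec A `gaze_recording` with a `screen_geometry` attached (or passed
#'   via `geometry`).
#' @param geometry Optional [screen_geometry()] overriding the recording's.
#' @return A `gaze_recording` in the target unit.
#' @examples
#' g <- screen_geometry(65, 52.7, 29.6, 1920, 1080)
#' rec <- as_gaze_recording(
#'   data.frame(time_ms = 0:1, x = c(960, 1000), y = 540),
#'   unit = "px", geometry = g
#' )
#' pixels_to_degrees(rec)
#' @export
pixels_to_degrees <- function(rec, geometry = NULL) {
  assert_recording(rec)
  if (identical(gaze_unit(rec), "prop")) rec <- proportion_to_pixels(rec, geometry)
  if (!identical(gaze_unit(rec), "px")) {
    stop_unit(paste0("Expected a recording in pixels (or screen proportion); got '",
                     gaze_unit(rec), "'."))
  }
  g <- geometry %||% gaze_geometry(rec)
  if (is.null(g)) stop_config("Pixel-to-degree conversion requires a screen_geometry.")
  cm_per_px_x <- g$screen_width_cm / g$res_x_px
  cm_per_px_y <- g$screen_height_cm / g$res_y_px
  out <- rec
  out$x <- atan((rec$x - g$res_x_px / 2) * cm_per_px_x / g$distance_cm) * 180 / pi
  out$y <- atan((rec$y - g$res_y_px / 2) * cm_per_px_y / g$distance_cm) * 180 / pi
  attr(out, "unit") <- "deg"
  attr(out, "geometry") <- g
  out
}

#' @rdname pixels_to_degrees
#' @export
degrees_to_pixels <- function(rec, geometry = NULL) {
  assert_recording(rec)
  if (!identical(gaze_unit(rec), "deg")) {
    stop_unit("Expected a recording in degrees.")
  }
  g <- geometry %||% gaze_geometry(rec)
  if (is.null(g)) stop_config("Degree-to-pixel conversion requires a screen_geometry.")
  cm_per_px_x <- g$screen_width_cm / g$res_x_px
  cm_per_px_y <- g$screen_height_cm / g$res_y_px
  out <- rec
  out$x <- tan(rec$x * pi / 180) * g$distance_cm / cm_per_px_x + g$res_x_px / 2
  out$y <- tan(rec$y * pi / 180) * g$distance_cm / cm_per_px_y + g$res_y_px / 2
  attr(out, "unit") <- "px"
  attr(out, "geometry") <- g
  out
}

#' @rdname pixels_to_degrees
#' @export
proportion_to_pixels <- function(rec, geometry = NULL) {
  assert_recording(rec)
  if (!identical(gaze_unit(rec), "prop")) {
    stop_unit("Expected a recording in screen proportion units.")
  }
  g <- geometry %||% gaze_geometry(rec)
  if (is.null(g)) stop_config("Proportion-to-pixel conversion requires a screen_geometry.")
  out <- rec
  out$x <- rec$x * g$res_x_px
  out$y <- rec$y * g$res_y_px
  attr(out, "unit") <- "px"
  attr(out, "geometry") <- g
  out
}
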