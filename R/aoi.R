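# Areas of interest: named rectangular or elliptical screen regions over
# which fixation counts, dwell time and entry latencies are accumulated.

#' Define rectangular and elliptical areas of interest
#'
#' An AOI set is a tibble with one row per AOI; combine AOIs with
#' `dplyr::bind_rows()`. Names must be unique within a set and the unit tag
#' must match the data the set is applied to.
#'
#' @param name AOI name, unique within a set.
#' @param x_min,y_min,x_max,y_max Rectangle bounds (inclusive).
#' @param center_x,center_y,radius_x,radius_y Ellipse center and semi-axes.
#' @param unit Coordinate unit tag (`"deg"`, `"px"` or `"prop"`).
#' @return A one-row tibble of class `aoi_set`.
#' @examples
#' aois <- dplyr::bind_rows(
#'   aoi_rectangle("left", -10, -5, -2, 5),
#'   aoi_ellipse("right", 6, 0, 3, 4))
#' @export
aoi_rectangle <- function(name, x_min, y_min, x_max, y_max, unit = "deg") {
  if (x_max <= x_min || y_max <= y_min) {
    stop_param("Rectangle AOI must have positive extents.")
  }
  new_aoi_set(tibble::tibble(
    name = name, shape = "rectangle", x_min = x_min, y_min = y_min,
    x_max = x_max, y_max = y_max, center_x = NA_real_, center_y = NA_real_,
    radius_x = NA_real_, radius_y = NA_real_, unit = unit))
}

#' @rdname aoi_rectangle
#' @export
aoi_ellipse <- function(name, center_x, center_y, radius_x, radius_y,
                        unit = "deg") {
  if (radius_x <= 0 || radius_y <= 0) {
    stop_param("Ellipse AOI must have positive radii.")
  }
  new_aoi_set(tibble::tibble(
    name = name, shape = "ellipse", x_min = NA_real_, y_min = NA_real_,
    x_max = NA_real_, y_max = NA_real_, center_x = center_x,
    center_y = center_y, radius_x = radius_x, radius_y = radius_y,
    unit = unit))
}

new_aoi_set <- function(df) {
  out <- tibble::as_tibble(df)
  if (!inherits(out, "aoi_set")) class(out) <- c("aoi_set", class(out))
  out
}

assert_aoi_set <- function(aois) {
  if (!is.data.frame(aois) || !all(c("name", "shape", "unit") %in% names(aois))) {
    stop_input("Expected an AOI set (see aoi_rectangle()/aoi_ellipse()).")
  }
  if (anyDuplicated(aois$name)) stop_param("AOI names must be unique within a set.")
  invisible(aois)
}

#' Test whether points fall inside an AOI
#'
#' Rectangle membership is `x_min <= x <= x_max` and `y_min <= y <= y_max`;
#' ellipse membership is `((x - cx)/rx)^2 + ((y - cy)/ry)^2 <= 1`. All
#' boundaries are inclusive.
#'
#' @param x,y Point coordinates (vectorized).
#' @param aoi A single-row AOI set.
#' @param unit Unit of the points, checked against the AOI's tag.
#' @return Logical vector.
#' @export
point_in_aoi <- function(x, y, aoi, unit = NULL) {
  assert_aoi_set(aoi)
  if (nrow(aoi) != 1) stop_input("point_in_aoi() expects a single AOI row.")
  if (!is.null(unit) && !identical(unit, aoi$unit)) {
    stop_unit(sprintf("Point unit '%s' does not match AOI unit '%s'.",
                      unit, aoi$unit))
  }
  if (aoi$shape == "rectangle") {
    x >= aoi$x_min & x <= aoi$x_max & y >= aoi$y_min & y <= aoi$y_max
  } else {
    ((x - aoi$center_x) / aoi$radius_x)^2 +
      ((y - aoi$center_y) / aoi$radius_y)^2 <= 1
  }
}

#' Read and write AOI sets as JSON
#'
#' The file format is a JSON array of objects with `name`, `shape`, `coords`
#' and `unit` fields.
#'
#' @param aois An `aoi_set`.
#' @param path JSON file path.
#' @return `read_aois()` returns an `aoi_set`; `write_aois()` returns `path`
#'   invisibly.
#' @export
write_aois <- function(aois, path) {
  assert_aoi_set(aois)
  recs <- lapply(seq_len(nrow(aois)), function(i) {
    a <- aois[i, ]
    coords <- if (a$shape == "rectangle") {
      list(x_min = a$x_min, y_min = a$y_min, x_max = a$x_max, y_max = a$y_max)
    } else {
      list(center_x = a$center_x, center_y = a$center_y,
           radius_x = a$radius_x, radius_y = a$radius_y)
    }
    list(name = a$name, shape = a$shape, coords = coords, unit = a$unit)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aois
#' @export
read_aois <- function(path) {
  if (!file.exists(path)) stop_io(paste0("File not found: ", path))
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- dplyr::bind_rows(lapply(recs, function(r) {
    if (r$shape == "rectangle") {
      aoi_rectangle(r$name, r$coords$x_min, r$coords$y_min,
                    r$coords$x_max, r$coords$y_max, unit = r$unit)
    } else {
      aoi_ellipse(r$name, r$coords$center_x, r$coords$center_y,
                  r$coords$radius_x, r$coords$radius_y, unit = r$unit)
    }
  }))
  assert_aoi_set(out)
  new_aoi_set(out)
}

#' AOI statistics for fixations or raw samples
#'
#' In fixation mode (`data` is an `event_set`), a fixation belongs to an AOI
#' according to `membership`: by default its centroid lies inside
#' (alternatives: any constituent sample inside, or a majority of them,
#' both requiring `rec`). Counts and total fixation time accumulate over
#' fixations overlapping the segment, with durations clipped to the
#' segment; the latency to the first fixation inside an AOI (and to the
#' first fixation in no AOI) is measured from segment start, counting only
#' fixations that begin inside the segment. Fixations that started before
#' the segment contribute clipped time but not latency. In sample mode
#' (`data` is a `gaze_recording`), the dwell proportion of valid samples
#' inside each AOI is returned instead, along with a `"(outside)"` row so
#' proportions over disjoint AOIs sum to 1.
#'
#' Overlapping AOIs are allowed — a fixation may count in several — and are
#' flagged in the `overlapping` attribute so users aggregating proportions
#' are warned.
#'
#' @param data An `event_set` (fixation mode) or `gaze_recording` (sample
#'   mode).
#' @param aois An `aoi_set` in the same unit as `data`.
#' @param segment Time interval `c(start_ms, end_ms)`; defaults to the full
#'   data range.
#' @param membership Fixation-membership strategy: `"centroid"`,
#'   `"any-sample"` or `"majority-sample"`.
#' @param rec Source recording, required for the sample-based membership
#'   strategies.
#' @return A tibble of class `aoi_stats`, one row per AOI plus
#'   `"(outside)"`: `n_fixations`, `total_fixation_time_ms`,
#'   `latency_first_inside_ms`, `latency_first_outside_ms`,
#'   `dwell_proportion` (sample mode only; `NA` in fixation mode).
#'   Undefined latencies are reported as `NA`, never 0.
#' @export
aoi_test <- function(data, aois, segment = NULL,
                     membership = c("centroid", "any-sample", "majority-sample"),
                     rec = NULL) {
  membership <- match.arg(membership)
  assert_aoi_set(aois)
  sample_mode <- inherits(data, "gaze_recording")
  data_unit <- if (sample_mode) gaze_unit(data) else attr(data, "unit") %||% "deg"
  if (!all(aois$unit == data_unit)) {
    stop_unit(sprintf("AOI unit(s) [%s] do not match the data unit '%s'.",
                      paste(unique(aois$unit), collapse = ", "), data_unit))
  }
  if (is.null(segment)) {
    segment <- if (sample_mode) range(data$time_ms) else {
      if (nrow(data) == 0) c(0, 0) else c(min(data$onset_ms), max(data$offset_ms))
    }
  }
  if (segment[2] <= segment[1]) stop_input("Segment must have positive length.")

  if (sample_mode) {
    idx <- which(data$time_ms >= segment[1] & data$time_ms <= segment[2] & data$valid)
    x <- data$x[idx]; y <- data$y[idx]
    inside <- vapply(seq_len(nrow(aois)), function(k) {
      point_in_aoi(x, y, aois[k, ])
    }, logical(length(idx)))
    inside <- matrix(inside, nrow = length(idx))
    any_inside <- if (length(idx) > 0) rowSums(inside) > 0 else logical(0)
    dwell <- if (length(idx) > 0) colMeans(inside) else rep(NA_real_, nrow(aois))
    out <- tibble::tibble(
      name = c(aois$name, "(outside)"),
      n_fixations = NA_integer_,
      total_fixation_time_ms = NA_real_,
      latency_first_inside_ms = NA_real_,
      latency_first_outside_ms = NA_real_,
      dwell_proportion = c(dwell,
                           if (length(idx) > 0) mean(!any_inside) else NA_real_),
      n_samples = length(idx))
    attr(out, "overlapping") <- length(idx) > 0 && any(rowSums(inside) > 1)
    class(out) <- c("aoi_stats", class(out))
    return(out)
  }

  fx <- tibble::as_tibble(data)
  fx <- fx[fx$kind == "fixation", ]
  fx <- fx[fx$offset_ms > segment[1] & fx$onset_ms < segment[2], ]
  fx <- fx[order(fx$onset_ms), ]
  clip <- pmin(fx$offset_ms, segment[2]) - pmax(fx$onset_ms, segment[1])
  starts_inside_segment <- fx$onset_ms >= segment[1]

  member_of <- function(aoi) {
    if (membership == "centroid") {
      point_in_aoi(fx$x, fx$y, aoi)
    } else {
      if (is.null(rec)) {
        stop_config("Sample-based membership strategies require `rec`.")
      }
      vapply(seq_len(nrow(fx)), function(i) {
        idx <- which(rec$time_ms >= fx$onset_ms[i] &
                       rec$time_ms <= fx$offset_ms[i] & rec$valid)
        if (length(idx) == 0) return(FALSE)
        ins <- point_in_aoi(rec$x[idx], rec$y[idx], aoi)
        if (membership == "any-sample") any(ins) else mean(ins) > 0.5
      }, logical(1))
    }
  }

  membership_mat <- matrix(FALSE, nrow = nrow(fx), ncol = nrow(aois))
  for (k in seq_len(nrow(aois))) membership_mat[, k] <- member_of(aois[k, ])
  in_none <- if (nrow(fx) > 0) rowSums(membership_mat) == 0 else logical(0)
  lat_outside <- first_latency(fx, in_none & starts_inside_segment, segment[1])

  rows <- lapply(seq_len(nrow(aois)), function(k) {
    inside <- membership_mat[, k]
    tibble::tibble(
      name = aois$name[k],
      n_fixations = sum(inside),
      total_fixation_time_ms = sum(clip[inside]),
      latency_first_inside_ms =
        first_latency(fx, inside & starts_inside_segment, segment[1]),
      latency_first_outside_ms = first_latency(
        fx, !inside & starts_inside_segment, segment[1]),
      dwell_proportion = NA_real_,
      n_samples = NA_integer_)
  })
  out <- dplyr::bind_rows(c(rows, list(tibble::tibble(
    name = "(outside)",
    n_fixations = sum(in_none),
    total_fixation_time_ms = sum(clip[in_none]),
    latency_first_inside_ms = lat_outside,
    latency_first_outside_ms = NA_real_,
    dwell_proportion = NA_real_,
    n_samples = NA_integer_))))
  attr(out, "overlapping") <- nrow(fx) > 0 && any(rowSums(membership_mat) > 1)
  class(out) <- c("aoi_stats", class(out))
  out
}

first_latency <- function(fx, which_rows, seg_start) {
  hits <- fx$onset_ms[which_rows]
  if (length(hits) == 0) NA_real_ else min(hits) - seg_start
}
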