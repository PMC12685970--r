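# Event sets: the common output container of all four classifiers.
#
# An event_set is a tibble with one row per classified event, sorted by
# onset. Fixations carry a centroid (`x`, `y`, mean of valid constituent
# samples), within-event sample-to-sample RMSD and the proportion of
# originally-missing constituent samples; saccades carry amplitude and peak
# velocity. `sample_time_ms` counts constituent-sample time only, so merged
# fixations keep it additive even though their span absorbs the gap.

event_columns <- c("kind", "onset_ms", "offset_ms", "duration_ms", "x", "y",
                   "amplitude_deg", "peak_velocity_dps", "rmsd_deg",
                   "prop_missing", "n_samples", "sample_time_ms", "algorithm")

empty_event_frame <- function() {
  tibble::tibble(
    kind = character(), onset_ms = numeric(), offset_ms = numeric(),
    duration_ms = numeric(), x = numeric(), y = numeric(),
    amplitude_deg = numeric(), peak_velocity_dps = numeric(),
    rmsd_deg = numeric(), prop_missing = numeric(), n_samples = integer(),
    sample_time_ms = numeric(), algorithm = character())
}

new_event_set <- function(df, algorithm, params = list(), unit = "deg") {
  out <- tibble::as_tibble(df)
  if (nrow(out) > 0) out <- out[order(out$onset_ms), ]
  attr(out, "params") <- params
  attr(out, "unit") <- unit
  class(out) <- c("event_set", class(out))
  out
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d fixations, %d saccades (%s)\n",
              sum(x$kind == "fixation"), sum(x$kind == "saccade"),
              paste(unique(x$algorithm), collapse = ", ")))
  NextMethod()
}

#' Extract fixations or saccades from an event set
#'
#' @param events An `event_set`.
#' @return The subset of rows of the given kind, still an `event_set`.
#' @export
fixations <- function(events) {
  assert_event_set(events)
  keep_event_attrs(events[events$kind == "fixation", ], events)
}

#' @rdname fixations
#' @export
saccades <- function(events) {
  assert_event_set(events)
  keep_event_attrs(events[events$kind == "saccade", ], events)
}

keep_event_attrs <- function(out, template) {
  attr(out, "params") <- attr(template, "params")
  attr(out, "unit") <- attr(template, "unit")
  if (!inherits(out, "event_set")) class(out) <- c("event_set", class(out))
  out
}

assert_event_set <- function(events) {
  if (!inherits(events, "event_set") && !is.data.frame(events)) {
    stop_input("Expected an event_set.")
  }
  invisible(events)
}

# originally-missing flags: invalid now, or valid only by interpolation
missing_flags <- function(rec) !rec$valid | rec$interpolated

# Metrics for one event spanning sample indices i0..i1 (inclusive).
event_row <- function(rec, i0, i1, kind, vel = NULL, dt_med = NULL) {
  idx <- i0:i1
  t <- rec$time_ms
  ok <- rec$valid[idx]
  miss <- missing_flags(rec)[idx]
  dt_med <- dt_med %||% sample_interval_ms(rec)
  x <- rec$x[idx]; y <- rec$y[idx]
  pair_ok <- ok[-1] & ok[-length(ok)]
  if (length(idx) >= 2 && any(pair_ok)) {
    d2 <- (diff(x)^2 + diff(y)^2)[pair_ok]
    rmsd <- sqrt(mean(d2))
  } else {
    rmsd <- NA_real_
  }
  if (kind == "fixation") {
    cx <- if (any(ok)) mean(x[ok]) else NA_real_
    cy <- if (any(ok)) mean(y[ok]) else NA_real_
    amp <- NA_real_; pv <- NA_real_
  } else {
    cx <- NA_real_; cy <- NA_real_
    vi <- which(ok)
    amp <- if (length(vi) >= 2) {
      sqrt((x[vi[length(vi)]] - x[vi[1]])^2 + (y[vi[length(vi)]] - y[vi[1]])^2)
    } else NA_real_
    pv <- if (!is.null(vel)) {
      vv <- vel$velocity_dps[idx]
      if (all(is.na(vv))) NA_real_ else max(vv, na.rm = TRUE)
    } else NA_real_
  }
  tibble::tibble(
    kind = kind, onset_ms = t[i0], offset_ms = t[i1],
    duration_ms = t[i1] - t[i0], x = cx, y = cy, amplitude_deg = amp,
    peak_velocity_dps = pv, rmsd_deg = rmsd, prop_missing = mean(miss),
    n_samples = length(idx), sample_time_ms = length(idx) * dt_med)
}

# Build an event set from a span table (columns i0, i1, kind).
build_event_set <- function(rec, spans, algorithm, params = list(), vel = NULL) {
  dt_med <- sample_interval_ms(rec)
  rows <- if (nrow(spans) == 0) {
    empty_event_frame()
  } else {
    dplyr::bind_rows(purrr::pmap(
      list(spans$i0, spans$i1, spans$kind),
      function(i0, i1, kind) event_row(rec, i0, i1, kind, vel, dt_med)))
  }
  rows$algorithm <- rep(algorithm, nrow(rows))
  new_event_set(rows, algorithm = algorithm, params = params,
                unit = gaze_unit(rec))
}

# Saccade spans between consecutive fixation spans, used by the dispersion
# and clustering classifiers which do not label saccades directly. These
# events exist so latency definitions work uniformly; they carry positional
# metrics but no velocity unless a trace is supplied.
interfixation_saccade_spans <- function(fix_spans) {
  if (nrow(fix_spans) < 2) {
    return(tibble::tibble(i0 = integer(), i1 = integer(), kind = character()))
  }
  fs <- fix_spans[order(fix_spans$i0), ]
  tibble::tibble(
    i0 = fs$i1[-nrow(fs)],
    i1 = fs$i0[-1],
    kind = "saccade")
}

run_spans <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  tibble::tibble(i0 = ends - r$lengths + 1L, i1 = ends, value = r$values)
}

#' Write an event table to CSV
#'
#' One row per event with the producing algorithm and its parameters
#' serialized into `#`-prefixed header comments, so the file is
#' self-describing. [read_events_table()] restores the table.
#'
#' @param events An `event_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(events, path) {
  assert_event_set(events)
  params <- attr(events, "params") %||% list()
  df <- tibble::as_tibble(events)
  class(df) <- setdiff(class(df), "event_set")
  attr(df, "params") <- NULL
  body <- readr::format_csv(df[, intersect(event_columns, names(df))])
  hdr <- c(
    paste0("# algorithm: ", paste(unique(events$algorithm), collapse = ",")),
    paste0("# params: ", jsonlite::toJSON(params, auto_unbox = TRUE)),
    paste0("# unit: ", attr(events, "unit") %||% "deg"))
  tryCatch(writeLines(c(hdr, sub("\n$", "", body)), path),
           error = function(e) stop_io(conditionMessage(e)))
  invisible(path)
}

#' Read an event table written by [write_events_table()]
#'
#' @param path Path to an events CSV.
#' @return An `event_set` tibble.
#' @export
read_events_table <- function(path) {
  if (!file.exists(path)) stop_io(paste0("File not found: ", path))
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    line <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(line) == 0) return(NULL)
    sub(paste0("^# ", key, ": "), "", line[1])
  }
  params <- tryCatch(jsonlite::fromJSON(get_field("params") %||% "{}"),
                     error = function(e) list())
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  df$kind <- as.character(df$kind)
  df$algorithm <- as.character(df$algorithm)
  new_event_set(df, algorithm = get_field("algorithm") %||% "unknown",
                params = params, unit = get_field("unit") %||% "deg")
}
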