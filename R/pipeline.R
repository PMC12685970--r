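# One-call pipeline: pre-process -> classify (one or many algorithms) ->
# post-process -> quality/AOI summaries -> optional plots, driven by a
# validated configuration and recorded in a run manifest.

known_config_keys <- c("input", "column_map", "unit", "time_unit", "geometry",
                       "seed", "preprocess", "downsample_hz", "algorithms",
                       "ivt", "idt", "adaptive", "i2mc", "postprocess",
                       "aois", "segment", "plots", "output_dir")

#' Build or load a validated pipeline configuration
#'
#' A run configuration is a named list (or a YAML/JSON file holding one)
#' with keys: `input` (gaze CSV path), `column_map`, `unit`, `time_unit`,
#' `geometry` (screen_geometry fields), `seed`, `preprocess`
#' ([preprocess_params()] fields), `downsample_hz`, `algorithms` (subset of
#' `ivt`, `idt`, `adaptive`, `i2mc`), per-algorithm parameter blocks,
#' `postprocess` (`merge_dist_deg`, `merge_gap_ms`, `trim_ms`,
#' `min_fixation_ms`, `max_prop_missing`), `aois` (JSON path), `segment`,
#' `plots` (logical) and `output_dir`. Unknown keys are rejected, and the
#' input path is checked before any computation. Omitted parameters take
#' the package defaults.
#'
#' @param config A named list, or path to a `.yaml`/`.yml`/`.json` file.
#' @return The validated configuration, classed `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_io(paste0("Config file not found: ", config))
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop_config("Configuration must be a named list or a file path.")
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown) > 0) {
    stop_config(paste0("Unknown configuration key(s): ",
                       paste(unknown, collapse = ", ")))
  }
  if (is.null(config$input)) stop_config("Configuration is missing `input`.")
  if (!file.exists(config$input)) {
    stop_config(paste0("Input file not found: ", config$input))
  }
  config$algorithms <- config$algorithms %||% "ivt"
  bad <- setdiff(config$algorithms, c("ivt", "idt", "adaptive", "i2mc"))
  if (length(bad) > 0) {
    stop_config(paste0("Unknown algorithm(s): ", paste(bad, collapse = ", ")))
  }
  config$unit <- config$unit %||% "deg"
  config$seed <- config$seed %||% 1L
  config$output_dir <- config$output_dir %||% tempfile("gazekit-run-")
  structure(config, class = "run_config")
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes pre-processing, event classification with each configured
#' algorithm, post-processing, the per-algorithm quality summary, pairwise
#' event-stream comparisons (when more than one algorithm ran), optional
#' AOI statistics and optional plots, writing every product under
#' `output_dir`. A JSON manifest records the package version, the full
#' parameter set and an MD5 hash of every output file, so an identical
#' configuration on identical input yields an identical manifest and the
#' manifest alone documents how to re-run the analysis.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = c("gazekit_pipeline_error", "gazekit_error"))
    })
  }

  geometry <- if (!is.null(cfg$geometry)) do.call(screen_geometry, cfg$geometry)
  rec <- stage("read", read_gaze_table(
    cfg$input,
    column_map = cfg$column_map %||% list(t = "t", x = "x", y = "y"),
    unit = cfg$unit, geometry = geometry,
    time_unit = cfg$time_unit %||% "ms"))
  if (gaze_unit(rec) != "deg") rec <- stage("convert", pixels_to_degrees(rec))

  pp <- do.call(preprocess_params, cfg$preprocess %||% list())
  rec_pp <- stage("preprocess", preprocess_gaze(rec, pp))
  if (!is.null(cfg$downsample_hz)) {
    rec_pp <- stage("downsample", downsample_gaze(rec_pp, cfg$downsample_hz))
  }
  preprocessed_path <- file.path(cfg$output_dir, "preprocessed.csv")
  write_gaze_table(rec_pp, preprocessed_path)

  classifiers <- list(ivt = classify_ivt, idt = classify_idt,
                      adaptive = classify_adaptive, i2mc = classify_i2mc)
  param_builders <- list(ivt = ivt_params, idt = idt_params,
                         adaptive = adaptive_params, i2mc = i2mc_params)
  sets <- list()
  event_paths <- character(0)
  for (alg in cfg$algorithms) {
    params <- do.call(param_builders[[alg]], cfg[[alg]] %||% list())
    ev <- stage(alg, classifiers[[alg]](rec_pp, params))
    post <- cfg$postprocess
    if (!is.null(post)) {
      ev <- stage("postprocess", {
        if (!is.null(post$merge_dist_deg)) {
          ev <- merge_adjacent_fixations(ev, rec = rec_pp,
                                         max_dist_deg = post$merge_dist_deg,
                                         max_gap_ms = post$merge_gap_ms %||% 50)
        }
        if (!is.null(post$trim_ms) && post$trim_ms > 0) {
          ev <- trim_fixations(ev, rec = rec_pp, trim_ms = post$trim_ms)
        }
        if (!is.null(post$min_fixation_ms) || !is.null(post$max_prop_missing)) {
          ev <- drop_fixations(ev,
                               min_duration_ms = post$min_fixation_ms %||% 0,
                               max_prop_missing = post$max_prop_missing %||% 1)
        }
        ev
      })
    }
    sets[[alg]] <- ev
    path <- file.path(cfg$output_dir, paste0("events_", alg, ".csv"))
    write_events_table(ev, path)
    event_paths <- c(event_paths, path)
  }

  summary_path <- file.path(cfg$output_dir, "summary.csv")
  summ <- summarize_algorithms(sets)
  readr::write_csv(tibble::as_tibble(summ), summary_path)

  comparison_path <- NULL
  if (length(sets) >= 2) {
    pairs <- utils::combn(names(sets), 2, simplify = FALSE)
    comps <- lapply(pairs, function(pr) {
      cmp <- compare_event_streams(sets[[pr[1]]], sets[[pr[2]]])
      c(list(reference = pr[1], comparison = pr[2]),
        as.list(tibble::as_tibble(cmp)))
    })
    comparison_path <- file.path(cfg$output_dir, "comparison.json")
    jsonlite::write_json(comps, comparison_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  }

  aoi_path <- NULL
  if (!is.null(cfg$aois)) {
    aois <- stage("aoi", read_aois(cfg$aois))
    stats <- stage("aoi", aoi_test(sets[[1]], aois,
                                   segment = cfg$segment))
    aoi_path <- file.path(cfg$output_dir, "aoi_stats.csv")
    readr::write_csv(tibble::as_tibble(stats), aoi_path)
  }

  plot_paths <- character(0)
  if (isTRUE(cfg$plots)) {
    plot_paths <- c(
      plot_timeseries(rec_pp, sets = sets,
                      out = file.path(cfg$output_dir, "timeseries.png")),
      plot_fixations_2d(rec_pp, sets,
                        out = file.path(cfg$output_dir, "fixations_2d.png")),
      plot_algorithm_quality(summ,
                             out = file.path(cfg$output_dir, "quality.png")))
  }

  outputs <- c(preprocessed_path, event_paths, summary_path, comparison_path,
               aoi_path, plot_paths)
  manifest <- list(
    package = "gazekit",
    version = as.character(utils::packageVersion("gazekit")),
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(manifest)
}
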