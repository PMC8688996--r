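# End-to-end orchestration: preparation -> segmentation -> features ->
# goal metrics -> variable selection and LOO-CV estimation, for a cohort of
# laps, with file import/export for the command-line interface.

lap_scenario_meta <- function(lap) {
  sc <- lap$scenario
  list(technique = sc$technique, pre_static = sc$pre_static,
       parallax_h = sc$parallax_h, parallax_d0 = sc$parallax_d0)
}

process_lap <- function(lap, meta_row, phase_source, gain = 0.1,
                        pool_length = 25) {
  sc <- lap$scenario
  prep <- prepare_imu(lap$imu_sensor, lap$calibration,
                      static_window = c(lap$imu_sensor$t[1],
                                        lap$imu_sensor$t[1] + sc$pre_static),
                      gain = gain)
  technique <- sc$technique
  if (phase_source == "imu") {
    bounds <- detect_lap_bounds(prep$global)
    ann <- segment_phases(prep$global, bounds, technique)
    cycles <- separate_cycles(prep$anatomical, ann$phases$Swim, technique)
  } else {
    if (is.null(lap$annotation)) stop("no reference annotation available")
    ann <- segment_phases(NULL, NULL, technique, annotation = lap$annotation)
    cycles <- lap$cycles_true %||%
      separate_cycles(prep$anatomical, ann$phases$Swim, technique)
  }
  feats <- extract_micro_variables(prep$global, prep$anatomical, ann, cycles,
                                   technique, meta = meta_row)
  goals <- NULL
  if (!is.null(lap$reference)) {
    ref <- lap$reference
    if (!is_corrected(ref)) {
      ref <- correct_parallax(ref, h = sc$parallax_h, d0 = sc$parallax_d0)
    }
    # scalar goal metrics within the reference (camera-style) annotation when
    # available, per-cycle velocities over the cycles used for the features
    ann_goal <- lap$annotation %||% ann
    goals <- compute_goal_metrics(ref, ann_goal, cycles,
                                  pool_length = pool_length)
  }
  list(features = feats$lap, cycle_features = feats$cycles, goals = goals,
       annotation = ann, cycles = cycles)
}

#' Run the full performance-evaluation pipeline on a cohort
#'
#' For every lap: data preparation (calibration, orientation fusion, global
#' frame), phase segmentation (from the IMU or from the stored reference
#' annotation), stroke-cycle separation, micro-variable extraction and goal
#' metric computation from the reference trace; then, per goal metric,
#' normalization, VIF filtering, LASSO selection and LOO-CV regression.
#' Laps failing a stage are dropped and logged with the stage and reason.
#'
#' @param cohort A `swim_cohort` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param phase_source `"imu"` (detector) or `"annotation"` (stored
#'   reference intervals).
#' @param targets Goal metrics to model; default all eight.
#' @param gain Orientation fusion gain.
#' @param pool_length Pool length (m).
#' @param vif_threshold VIF threshold.
#' @param seed Seed for the cross-validation fold draws.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @param quiet Suppress progress messages.
#' @return A list of class `swim_pipeline_result` with `features`,
#'   `cycle_features`, `goals`, `cycle_goals`, `reports` (one
#'   `swim_target_report` per target), `dropped` (tibble `lap_id`, `stage`,
#'   `reason`) and `summary` (one row per target from `glance()`).
#' @export
run_pipeline <- function(cohort, phase_source = c("imu", "annotation"),
                         targets = GOAL_TARGETS, gain = 0.1, pool_length = 25,
                         vif_threshold = 10, seed = 1L, out_dir = NULL,
                         quiet = FALSE) {
  phase_source <- match.arg(phase_source)
  stopifnot(inherits(cohort, "swim_cohort"))
  say <- function(...) if (!quiet) message(...)
  feats <- list(); cyc_feats <- list(); goal_rows <- list(); cyc_goals <- list()
  dropped <- list()
  for (i in seq_along(cohort$laps)) {
    meta_row <- cohort$meta[i, ]
    res <- tryCatch(
      process_lap(cohort$laps[[i]], meta_row, phase_source,
                  gain = gain, pool_length = pool_length),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      say(sprintf("lap %d dropped: %s", meta_row$lap_id, conditionMessage(res)))
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        lap_id = meta_row$lap_id, stage = "processing",
        reason = conditionMessage(res))
      next
    }
    if (nrow(res$features) == 0L) {
      dropped[[length(dropped) + 1L]] <- tibble::tibble(
        lap_id = meta_row$lap_id, stage = "features",
        reason = "undefined micro-variable")
      next
    }
    feats[[length(feats) + 1L]] <- res$features
    cyc_feats[[length(cyc_feats) + 1L]] <- res$cycle_features
    if (!is.null(res$goals)) {
      g <- tibble::as_tibble(res$goals)
      cyc <- g$swim_vavg_cycle[[1]]
      g$swim_vavg_cycle <- NULL
      g$lap_id <- meta_row$lap_id
      goal_rows[[length(goal_rows) + 1L]] <- g
      cyc$lap_id <- meta_row$lap_id
      cyc_goals[[length(cyc_goals) + 1L]] <- cyc
    }
  }
  features <- dplyr::bind_rows(feats)
  cycle_features <- dplyr::bind_rows(cyc_feats)
  goals <- dplyr::bind_rows(goal_rows)
  cycle_goals <- dplyr::bind_rows(cyc_goals)
  dropped <- if (length(dropped)) dplyr::bind_rows(dropped) else
    tibble::tibble(lap_id = integer(), stage = character(), reason = character())

  reports <- list()
  if (nrow(goals) > 0) {
    for (tg in targets) {
      say("modelling target: ", tg)
      set.seed(seed)
      rep_t <- tryCatch({
        if (identical(tg, "swim_vavg_cycle")) {
          estimate_goal_metric(cycle_features, cycle_goals, tg,
                               vif_threshold = vif_threshold,
                               loo_lambda = "fixed")
        } else {
          estimate_goal_metric(features, goals, tg,
                               vif_threshold = vif_threshold,
                               loo_lambda = "nested")
        }
      }, error = function(e) e)
      if (inherits(rep_t, "error")) {
        say(sprintf("target %s failed: %s", tg, conditionMessage(rep_t)))
        dropped <- dplyr::bind_rows(dropped, tibble::tibble(
          lap_id = NA_integer_, stage = paste0("model:", tg),
          reason = conditionMessage(rep_t)))
      } else {
        reports[[tg]] <- rep_t
      }
    }
  } else {
    say("no reference traces: goal-metric and model stages skipped")
  }
  summary <- purrr::map_dfr(reports, function(r) glance(r$regression))
  out <- structure(list(features = features, cycle_features = cycle_features,
                        goals = goals, cycle_goals = cycle_goals,
                        reports = reports, dropped = dropped,
                        summary = summary, phase_source = phase_source),
                   class = "swim_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' @method print swim_pipeline_result
#' @export
print.swim_pipeline_result <- function(x, ...) {
  cat(sprintf("<swim_pipeline_result: %d laps, %d cycles, phases from %s>\n",
              nrow(x$features), nrow(x$cycle_features), x$phase_source))
  if (nrow(x$summary)) print(x$summary)
  if (nrow(x$dropped)) cat(sprintf("%d observation(s) dropped\n", nrow(x$dropped)))
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' @param result A `swim_pipeline_result`.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(result$features, file.path(dir, "features.csv"))
  if (nrow(result$cycle_features)) {
    readr::write_csv(result$cycle_features, file.path(dir, "cycle_features.csv"),
                     progress = FALSE)
  }
  if (nrow(result$goals)) {
    readr::write_csv(result$goals, file.path(dir, "goals.csv"), progress = FALSE)
    readr::write_csv(result$cycle_goals, file.path(dir, "cycle_goals.csv"),
                     progress = FALSE)
  }
  for (tg in names(result$reports)) {
    write_target_report_json(result$reports[[tg]],
                             file.path(dir, paste0("report_", tg, ".json")))
  }
  if (nrow(result$summary)) {
    readr::write_csv(result$summary, file.path(dir, "summary.csv"),
                     progress = FALSE)
  }
  readr::write_csv(result$dropped, file.path(dir, "dropped.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Write and read a cohort as plain-text files
#'
#' Each lap gets a directory `lap_0001/` with `imu.csv` (+ YAML sidecar),
#' `reference.csv`, `annotation.json` (including true cycle boundaries),
#' `calibration.yaml` and `meta.yaml`; `meta.csv` and `swimmers.csv` sit at
#' the top level.
#'
#' @param cohort A `swim_cohort`.
#' @param dir Target directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$meta, file.path(dir, "meta.csv"), progress = FALSE)
  if (!is.null(cohort$swimmers)) {
    readr::write_csv(cohort$swimmers, file.path(dir, "swimmers.csv"),
                     progress = FALSE)
  }
  for (i in seq_along(cohort$laps)) {
    lap <- cohort$laps[[i]]
    ld <- file.path(dir, sprintf("lap_%04d", cohort$meta$lap_id[i]))
    dir.create(ld, showWarnings = FALSE)
    write_imu_csv(lap$imu_sensor, file.path(ld, "imu.csv"))
    if (!is.null(lap$reference)) {
      write_reference_csv(lap$reference, file.path(ld, "reference.csv"))
    }
    if (!is.null(lap$annotation)) {
      write_annotation_json(lap$annotation, file.path(ld, "annotation.json"),
                            cycles = lap$cycles_true)
    }
    write_calibration_yaml(lap$calibration, file.path(ld, "calibration.yaml"))
    yaml::write_yaml(lap_scenario_meta(lap), file.path(ld, "meta.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "meta.csv"), show_col_types = FALSE,
                          progress = FALSE)
  sw_path <- file.path(dir, "swimmers.csv")
  swimmers <- if (file.exists(sw_path)) {
    readr::read_csv(sw_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  laps <- purrr::map(seq_len(nrow(meta)), function(i) {
    ld <- file.path(dir, sprintf("lap_%04d", meta$lap_id[i]))
    sc <- yaml::read_yaml(file.path(ld, "meta.yaml"))
    ann <- NULL; cyc <- NULL
    ann_path <- file.path(ld, "annotation.json")
    if (file.exists(ann_path)) {
      aj <- read_annotation_json(ann_path)
      ann <- aj$annotation; cyc <- aj$cycles
    }
    ref_path <- file.path(ld, "reference.csv")
    list(
      imu_sensor = read_imu_csv(file.path(ld, "imu.csv")),
      calibration = read_calibration_yaml(file.path(ld, "calibration.yaml")),
      reference = if (file.exists(ref_path)) read_reference_csv(ref_path) else NULL,
      annotation = ann, cycles_true = cyc,
      scenario = sc
    )
  })
  structure(list(laps = laps, meta = meta, swimmers = swimmers),
            class = "swim_cohort")
}

#' @method print swim_cohort
#' @export
print.swim_cohort <- function(x, ...) {
  cat(sprintf("<swim_cohort: %d laps, %d swimmer(s), technique(s): %s>\n",
              length(x$laps), length(unique(x$meta$swimmer)),
              paste(unique(x$meta$technique), collapse = ", ")))
  invisible(x)
}
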