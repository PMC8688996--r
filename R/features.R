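# Phase-based kinematic micro-variables.
#
# Variables are computed on global-frame signals within half-open phase
# intervals and named "<Phase>.<Func>(<Signal>)", e.g. "Push.Mean(AccY)".
# Each belongs to one of four categories: propulsion, posture, efficiency,
# duration_rate. Angles are reported in degrees; accelerations in m/s^2;
# angular velocities in rad/s; rates in 1/min; durations in s.

#' Basic signal statistics over an interval
#'
#' Mean, range (max - min), population standard deviation and maximum of the
#' samples falling in the half-open interval `[on, off)`.
#'
#' @param x Numeric signal samples.
#' @param t Optional time vector matching `x`; required when `interval` is
#'   given.
#' @param interval Optional `c(on, off)` window (s).
#' @return A tibble with columns `mean`, `range`, `sd`, `max`.
#' @export
signal_stats <- function(x, t = NULL, interval = NULL) {
  if (!is.null(interval)) {
    if (is.null(t)) stop("t is required when interval is given")
    x <- x[t >= interval[1] & t < interval[2]]
  }
  if (length(x) == 0L) stop("empty interval")
  n <- length(x)
  tibble::tibble(
    mean = mean(x),
    range = max(x) - min(x),
    sd = sqrt(sum((x - mean(x))^2) / n),
    max = max(x)
  )
}

window_idx <- function(t, interval) t >= interval[1] & t < interval[2]

trapz_win <- function(t, x, interval = NULL) {
  if (!is.null(interval)) {
    # integrals cover the closed interval so the full duration is integrated
    # (half-open windows are for sample membership in statistics)
    i <- t >= interval[1] & t <= interval[2]
    t <- t[i]; x <- x[i]
  }
  if (length(t) < 2L) stop("empty interval")
  pracma::trapz(t, x)
}

#' Net and propulsive forward-acceleration integrals
#'
#' `Int` is the trapezoidal integral of the forward acceleration over the
#' interval (net velocity change, m/s). `Momentum` is the mass-normalized
#' propulsive impulse: the integral of the positive part of the forward
#' acceleration only (m/s), distinct from `Int` whenever braking occurs.
#'
#' @param acc_y Forward (global Y) acceleration, m/s^2.
#' @param t Time vector (s).
#' @param interval Optional `c(on, off)` window.
#' @return A tibble with columns `int` and `momentum`.
#' @export
integral_and_momentum <- function(acc_y, t, interval = NULL) {
  tibble::tibble(
    int = trapz_win(t, acc_y, interval),
    momentum = trapz_win(t, pmax(acc_y, 0), interval)
  )
}

#' Acceleration efficiency ratios
#'
#' Time-integral ratios of the positive forward acceleration to the negative
#' forward acceleration (`eff`) and to the acceleration norm (`eff_dir`):
#' \deqn{Eff = \int \max(AccY, 0)\,dt \;/\; \int \max(-AccY, 0)\,dt}
#' \deqn{Eff_{dir} = \int \max(AccY, 0)\,dt \;/\; \int \lVert Acc \rVert\,dt}
#' A zero denominator yields `NA` (flagged undefined) with a warning.
#'
#' @param acc n x 3 matrix (or data frame) of global accelerations; the
#'   second column is the forward channel.
#' @param t Time vector (s).
#' @param interval Optional `c(on, off)` window.
#' @return A tibble with columns `eff`, `eff_dir`.
#' @export
efficiency_ratios <- function(acc, t, interval = NULL) {
  acc <- as.matrix(acc)
  pos <- trapz_win(t, pmax(acc[, 2], 0), interval)
  neg <- trapz_win(t, pmax(-acc[, 2], 0), interval)
  nrm <- trapz_win(t, sqrt(rowSums(acc^2)), interval)
  eff <- if (neg > 1e-9) pos / neg else NA_real_
  eff_dir <- if (nrm > 1e-9) pos / nrm else NA_real_
  if (is.na(eff) || is.na(eff_dir)) {
    warning("efficiency ratio undefined (zero denominator); flagged as NA")
  }
  tibble::tibble(eff = eff, eff_dir = eff_dir)
}

#' Forward velocity over the Swim phase from IMU acceleration
#'
#' Integrates the global forward acceleration from the lap start (zero
#' velocity at the wall) to anchor the velocity at the start of Swim, then
#' integrates across Swim and removes integration drift linearly so that the
#' net velocity change over the phase matches the zero-net-acceleration
#' steady-state constraint. Drift growth is the known failure mode of
#' double-integrated sacrum IMU data; the per-phase re-anchoring keeps it
#' bounded.
#'
#' @param rec Global-frame `imu_recording`.
#' @param ann A `phase_annotation`.
#' @return A tibble with `t` and `v` (m/s) covering the Swim phase.
#' @export
swim_forward_velocity <- function(rec, ann) {
  assert_frame(rec, "global")
  swim <- ann$phases$Swim
  pre <- window_idx(rec$t, c(ann$lap[1], swim[1]))
  if (!any(pre)) stop("empty interval")
  v_anchor <- pracma::trapz(rec$t[pre], rec$acc_y[pre])
  i <- window_idx(rec$t, swim)
  tt <- rec$t[i]
  v_raw <- v_anchor + pracma::cumtrapz(tt, rec$acc_y[i])[, 1]
  drift <- (v_raw[length(v_raw)] - v_raw[1]) / (tt[length(tt)] - tt[1])
  tibble::tibble(t = tt, v = v_raw - drift * (tt - tt[1]))
}

#' Distance per stroke over one cycle
#'
#' Displacement covered during a cycle: the time integral of the forward
#' velocity over the cycle interval.
#'
#' @param v_df Tibble with `t` and `v` (e.g. [swim_forward_velocity()] or a
#'   corrected reference trace).
#' @param cycle `c(on, off)` of the cycle (s).
#' @return DPS in metres.
#' @export
distance_per_stroke <- function(v_df, cycle) {
  if (diff(cycle) < 0.3) warning("cycle shorter than 0.3 s")
  trapz_win(v_df$t, v_df$v, cycle)
}

#' Kick events in an interval
#'
#' Kicks are peaks of the anatomical mediolateral angular velocity with
#' prominence above `prominence` rad/s.
#'
#' @param rec Anatomical-frame `imu_recording`.
#' @param interval `c(on, off)` window (s).
#' @param prominence Peak prominence threshold (rad/s), default 0.5.
#' @return A tibble with `count` and `rate` (1/min).
#' @export
count_kicks <- function(rec, interval, prominence = 0.5) {
  assert_frame(rec, "anatomical")
  i <- window_idx(rec$t, interval)
  x <- rec$gyr_x[i]
  pk <- pracma::findpeaks(x, minpeakheight = prominence)
  n <- if (is.null(pk)) 0L else nrow(pk)
  tibble::tibble(count = n, rate = 60 * n / diff(interval))
}

micro_funcs_stats <- c("Mean", "Range", "SD")

#' The micro-variable catalogue
#'
#' Enumerates every lap-level micro-variable emitted by
#' [extract_micro_variables()] for a technique, with its phase and category.
#' The column set is identical across techniques (techniques differ only in
#' the cycle-separation channel).
#'
#' @param technique Swimming technique.
#' @return A tibble with `name`, `phase`, `category`.
#' @export
micro_variable_catalogue <- function(technique = "front_crawl") {
  technique <- match.arg(technique, TECHNIQUES)
  rows <- list()
  add <- function(name, phase, category) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      name = name, phase = phase, category = category)
  }
  for (ph in PHASES) {
    for (fn in micro_funcs_stats) {
      for (sig in c("AccX", "AccY", "AccZ")) {
        add(sprintf("%s.%s(%s)", ph, fn, sig), ph, "propulsion")
      }
    }
    for (fn in c("Max", "Int", "Momentum")) {
      add(sprintf("%s.%s(AccY)", ph, fn), ph, "propulsion")
    }
    for (fn in micro_funcs_stats) {
      for (sig in c("theta", "phi")) {
        add(sprintf("%s.%s(%s)", ph, fn, sig), ph, "posture")
      }
    }
    add(sprintf("%s.Eff(AccY)", ph), ph, "efficiency")
    add(sprintf("%s.Eff_dir(AccY)", ph), ph, "efficiency")
    for (fn in micro_funcs_stats) {
      for (sig in c("GyrX", "GyrY", "GyrZ")) {
        add(sprintf("%s.%s(%s)", ph, fn, sig), ph, "duration_rate")
      }
    }
    add(sprintf("%s.Duration", ph), ph, "duration_rate")
  }
  add("StPr.KickRate", "StPr", "duration_rate")
  add("StPr.KickCount", "StPr", "duration_rate")
  add("Swim.DPS", "Swim", "efficiency")
  add("Swim.StrokeRate", "Swim", "duration_rate")
  add("Swim.StrokeCount", "Swim", "duration_rate")
  add("Swim.CycleDuration", "Swim", "duration_rate")
  dplyr::bind_rows(rows)
}

#' Per-cycle micro-variable catalogue
#'
#' @return A tibble with `name`, `category` for the cycle-level variables.
#' @export
cycle_variable_catalogue <- function() {
  rows <- list()
  add <- function(name, category) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(name = name, category = category)
  }
  for (fn in micro_funcs_stats) {
    for (sig in c("AccX", "AccY", "AccZ")) add(sprintf("Cycle.%s(%s)", fn, sig), "propulsion")
  }
  for (fn in c("Max", "Int", "Momentum")) add(sprintf("Cycle.%s(AccY)", fn), "propulsion")
  for (fn in micro_funcs_stats) {
    for (sig in c("theta", "phi")) add(sprintf("Cycle.%s(%s)", fn, sig), "posture")
  }
  add("Cycle.Eff(AccY)", "efficiency")
  add("Cycle.Eff_dir(AccY)", "efficiency")
  add("Cycle.DPS", "efficiency")
  for (fn in micro_funcs_stats) {
    for (sig in c("GyrX", "GyrY", "GyrZ")) add(sprintf("Cycle.%s(%s)", fn, sig), "duration_rate")
  }
  add("Cycle.Duration", "duration_rate")
  dplyr::bind_rows(rows)
}

phase_block <- function(rec, interval, prefix, kicks = NULL) {
  i <- window_idx(rec$t, interval)
  if (!any(i)) stop("empty interval for ", prefix)
  tt <- rec$t[i]
  out <- list()
  sigs <- list(AccX = rec$acc_x[i], AccY = rec$acc_y[i], AccZ = rec$acc_z[i])
  for (nm in names(sigs)) {
    s <- signal_stats(sigs[[nm]])
    out[[sprintf("%s.Mean(%s)", prefix, nm)]] <- s$mean
    out[[sprintf("%s.Range(%s)", prefix, nm)]] <- s$range
    out[[sprintf("%s.SD(%s)", prefix, nm)]] <- s$sd
  }
  out[[sprintf("%s.Max(AccY)", prefix)]] <- max(sigs$AccY)
  im <- integral_and_momentum(sigs$AccY, tt)
  out[[sprintf("%s.Int(AccY)", prefix)]] <- im$int
  out[[sprintf("%s.Momentum(AccY)", prefix)]] <- im$momentum
  for (nm in c("theta", "phi")) {
    s <- signal_stats(rec[[nm]][i] * 180 / pi)
    out[[sprintf("%s.Mean(%s)", prefix, nm)]] <- s$mean
    out[[sprintf("%s.Range(%s)", prefix, nm)]] <- s$range
    out[[sprintf("%s.SD(%s)", prefix, nm)]] <- s$sd
  }
  er <- suppressWarnings(efficiency_ratios(cbind(sigs$AccX, sigs$AccY, sigs$AccZ), tt))
  out[[sprintf("%s.Eff(AccY)", prefix)]] <- er$eff
  out[[sprintf("%s.Eff_dir(AccY)", prefix)]] <- er$eff_dir
  gyrs <- list(GyrX = rec$gyr_x[i], GyrY = rec$gyr_y[i], GyrZ = rec$gyr_z[i])
  for (nm in names(gyrs)) {
    s <- signal_stats(gyrs[[nm]])
    out[[sprintf("%s.Mean(%s)", prefix, nm)]] <- s$mean
    out[[sprintf("%s.Range(%s)", prefix, nm)]] <- s$range
    out[[sprintf("%s.SD(%s)", prefix, nm)]] <- s$sd
  }
  out[[sprintf("%s.Duration", prefix)]] <- diff(interval)
  out
}

#' Extract the micro-variable table for one lap
#'
#' Computes the full lap-level catalogue (see [micro_variable_catalogue()])
#' plus one row per stroke cycle of the cycle-level catalogue. The forward
#' velocity used for DPS comes from IMU integration
#' ([swim_forward_velocity()]) by default, or from a corrected reference
#' trace when `velocity` is supplied.
#'
#' @param rec_global Global-frame recording with Euler columns `theta`, `phi`.
#' @param rec_anatomical Anatomical-frame recording (cycle/kick channels).
#' @param ann A `phase_annotation`.
#' @param cycles A `cycle_set`.
#' @param technique Swimming technique.
#' @param meta Optional one-row tibble of metadata (swimmer, trial, pace, ...)
#'   prepended to the outputs.
#' @param velocity Optional tibble `t`, `v` overriding the IMU-derived
#'   forward velocity for DPS.
#' @param on_undefined `"drop"` (default) drops an observation containing an
#'   undefined variable with a warning; `"keep"` keeps the `NA`.
#' @return A list with `lap` (one-row tibble, or zero rows if dropped) and
#'   `cycles` (one row per retained cycle).
#' @export
extract_micro_variables <- function(rec_global, rec_anatomical, ann, cycles,
                                    technique, meta = NULL, velocity = NULL,
                                    on_undefined = c("drop", "keep")) {
  on_undefined <- match.arg(on_undefined)
  assert_frame(rec_global, "global")
  technique <- match.arg(technique, TECHNIQUES)
  if (is.null(rec_global$theta) || is.null(rec_global$phi)) {
    stop("rec_global must carry Euler angle columns (see prepare_imu())")
  }
  vals <- list()
  for (ph in PHASES) {
    vals <- c(vals, phase_block(rec_global, ann$phases[[ph]], ph))
  }
  kk <- count_kicks(rec_anatomical, ann$phases$StPr)
  vals[["StPr.KickRate"]] <- kk$rate
  vals[["StPr.KickCount"]] <- as.numeric(kk$count)
  ci <- cycle_intervals(cycles)
  v_df <- if (is.null(velocity)) swim_forward_velocity(rec_global, ann) else velocity
  dps <- vapply(seq_len(nrow(ci)), function(k) {
    suppressWarnings(distance_per_stroke(v_df, c(ci$on[k], ci$off[k])))
  }, numeric(1))
  swim_dur <- diff(ann$phases$Swim)
  vals[["Swim.DPS"]] <- mean(dps)
  vals[["Swim.StrokeRate"]] <- 60 * nrow(ci) / swim_dur
  vals[["Swim.StrokeCount"]] <- as.numeric(nrow(ci))
  vals[["Swim.CycleDuration"]] <- mean(ci$duration)

  lap_row <- tibble::as_tibble(vals)
  # order columns per catalogue
  lap_row <- lap_row[micro_variable_catalogue(technique)$name]
  if (anyNA(lap_row)) {
    bad <- names(lap_row)[vapply(lap_row, anyNA, logical(1))]
    if (on_undefined == "drop") {
      warning("dropping lap observation: undefined variable(s) ",
              paste(bad, collapse = ", "))
      lap_row <- lap_row[0, ]
    }
  }

  cyc_rows <- purrr::map_dfr(seq_len(nrow(ci)), function(k) {
    iv <- c(ci$on[k], ci$off[k])
    blk <- phase_block(rec_global, iv, "Cycle")
    blk[["Cycle.Duration"]] <- NULL
    row <- tibble::as_tibble(blk)
    row[["Cycle.DPS"]] <- dps[k]
    row[["Cycle.Duration"]] <- ci$duration[k]
    row[["cycle"]] <- k
    row
  })
  cyc_rows <- cyc_rows[c("cycle", cycle_variable_catalogue()$name)]
  drop_cyc <- apply(is.na(cyc_rows), 1, any)
  if (any(drop_cyc) && on_undefined == "drop") {
    warning(sprintf("dropping %d cycle observation(s) with undefined variables",
                    sum(drop_cyc)))
    cyc_rows <- cyc_rows[!drop_cyc, ]
  }
  if (!is.null(meta)) {
    lap_row <- if (nrow(lap_row)) dplyr::bind_cols(meta, lap_row) else lap_row
    if (nrow(cyc_rows)) cyc_rows <- dplyr::bind_cols(
      meta[rep(1, nrow(cyc_rows)), ], cyc_rows)
  }
  list(lap = lap_row, cycles = cyc_rows)
}

#' Write a feature table with its category sidecar
#'
#' @param features Feature tibble (metadata columns first).
#' @param path CSV path; the category map is written to
#'   `paste0(path, ".categories.json")`.
#' @param catalogue Catalogue tibble mapping `name` to `category`.
#' @export
write_feature_table <- function(features, path,
                                catalogue = micro_variable_catalogue()) {
  readr::write_csv(features, path, progress = FALSE)
  cats <- stats::setNames(as.list(catalogue$category), catalogue$name)
  jsonlite::write_json(cats, paste0(path, ".categories.json"), auto_unbox = TRUE)
  invisible(path)
}
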