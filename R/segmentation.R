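# Lap delimitation, phase segmentation and stroke-cycle separation.
#
# A 25 m lap starting with an in-water wall push-off is split into four
# contiguous half-open phases: Push (wall push-off), Glid (glide), StPr
# (stroke/kick preparation) and Swim (full swimming). Cycle separation uses
# successive positive peaks of the technique's anatomical angular-velocity
# channel: longitudinal (gyr_y) for front crawl and backstroke, mediolateral
# (gyr_x) for breaststroke and butterfly.

PHASES <- c("Push", "Glid", "StPr", "Swim")
TECHNIQUES <- c("front_crawl", "breaststroke", "butterfly", "backstroke")

#' Phase annotation for one lap
#'
#' @param lap `c(t_start, t_end)` in seconds.
#' @param phases Named list `Push`, `Glid`, `StPr`, `Swim`, each `c(on, off)`;
#'   half-open `[on, off)` intervals that must tile the lap.
#' @param source `"camera"`, `"imu"` or `"synthetic"`.
#' @return A list of class `phase_annotation`.
#' @export
phase_annotation <- function(lap, phases, source = c("imu", "camera", "synthetic")) {
  source <- match.arg(source)
  if (!identical(names(phases), PHASES)) {
    phases <- phases[PHASES]
    if (anyNA(names(phases))) stop("phases must contain Push, Glid, StPr, Swim")
  }
  b <- c(phases$Push[1], phases$Glid[1], phases$StPr[1], phases$Swim[1], phases$Swim[2])
  if (abs(phases$Push[1] - lap[1]) > 1e-9 || abs(phases$Swim[2] - lap[2]) > 1e-9) {
    stop("phases must span the lap: Push.on = lap start, Swim.off = lap end")
  }
  for (i in seq_len(3)) {
    if (abs(phases[[i]][2] - phases[[i + 1]][1]) > 1e-9) {
      stop(sprintf("phase intervals must be contiguous: %s.off != %s.on",
                   PHASES[i], PHASES[i + 1]))
    }
  }
  if (any(diff(b) <= 0)) {
    bad <- PHASES[which(diff(b) <= 0)[1]]
    stop(sprintf("phase '%s' has non-positive duration", bad))
  }
  structure(list(lap = as.numeric(lap),
                 phases = lapply(phases, as.numeric),
                 source = source),
            class = "phase_annotation")
}

#' @method print phase_annotation
#' @export
print.phase_annotation <- function(x, ...) {
  cat(sprintf("<phase_annotation source=%s lap=[%.2f, %.2f] s>\n",
              x$source, x$lap[1], x$lap[2]))
  for (p in PHASES) {
    cat(sprintf("  %s: [%.3f, %.3f)  %.3f s\n", p,
                x$phases[[p]][1], x$phases[[p]][2], diff(x$phases[[p]])))
  }
  invisible(x)
}

#' Durations of the four phases
#'
#' @param ann A `phase_annotation`.
#' @return A named numeric vector of durations (s).
#' @export
phase_durations <- function(ann) {
  vapply(ann$phases, function(p) p[2] - p[1], numeric(1))
}

#' Stroke-cycle boundaries within the Swim phase
#'
#' @param boundaries Strictly increasing times (s) inside the Swim interval;
#'   at least two, so at least one cycle is defined.
#' @param technique Swimming technique.
#' @return A list of class `cycle_set`.
#' @export
cycle_set <- function(boundaries, technique) {
  technique <- match.arg(technique, TECHNIQUES)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L) stop("no cycles detected: need at least 2 boundaries")
  if (any(diff(boundaries) <= 0)) stop("cycle boundaries must be strictly increasing")
  structure(list(boundaries = boundaries, technique = technique),
            class = "cycle_set")
}

#' Cycle intervals as a tibble
#'
#' @param cycles A `cycle_set`.
#' @return Tibble with `cycle`, `on`, `off`, `duration`.
#' @export
cycle_intervals <- function(cycles) {
  b <- cycles$boundaries
  tibble::tibble(cycle = seq_len(length(b) - 1L),
                 on = b[-length(b)], off = b[-1L],
                 duration = diff(b))
}

cycle_channel <- function(technique) {
  technique <- match.arg(technique, TECHNIQUES)
  # longitudinal angular velocity for alternating-arm strokes, mediolateral
  # for the simultaneous techniques
  if (technique %in% c("front_crawl", "backstroke")) "gyr_y" else "gyr_x"
}

moving_rms <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  k <- rep(1 / n, n)
  sq <- stats::filter(x^2, k, sides = 2)
  sq[is.na(sq)] <- x[is.na(sq)]^2
  sqrt(as.numeric(sq))
}

#' Detect the lap bounds from a global-frame recording
#'
#' The lap starts at the onset of the wall push-off burst (forward
#' acceleration above `theta_push` sustained for `min_burst` seconds) and ends
#' when sustained activity (gyroscope magnitude or forward acceleration above
#' thresholds) last occurs. Activity gaps up to `max_gap` seconds (the quiet
#' glide) are bridged. If a second activity region follows the first lap, the
#' first is returned with a warning.
#'
#' @param rec Global-frame `imu_recording`.
#' @param theta_push Push acceleration threshold (m/s^2), default 1.5.
#' @param min_burst Minimum burst duration (s), default 0.05.
#' @param theta_act Gyro activity threshold (rad/s), default 0.8.
#' @param max_gap Largest within-lap quiet gap (s), default 2.5.
#' @return `c(t_start, t_end)` in seconds.
#' @export
detect_lap_bounds <- function(rec, theta_push = 1.5, min_burst = 0.05,
                              theta_act = 0.8, max_gap = 2.5) {
  assert_frame(rec, "global")
  fs <- imu_fs(rec)
  # low-pass the forward channel so push-off vibration does not fragment
  # the burst
  ay_s <- lowpass(rec$acc_y, fs, 5)
  burst <- ay_s > theta_push
  r <- rle(burst)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= max(1L, round(min_burst * fs))
  if (!any(ok)) stop("no lap detected: no sustained push-off burst found")
  i_start <- starts[which(ok)[1]]
  t_start <- rec$t[i_start]

  gyr_mag <- sqrt(rec$gyr_x^2 + rec$gyr_y^2 + rec$gyr_z^2)
  active <- gyr_mag > theta_act | abs(rec$acc_y) > max(theta_push, 2.5)
  idx <- which(active & rec$t >= t_start)
  if (length(idx) == 0L) stop("no lap detected: no activity after push-off")
  gaps <- which(diff(rec$t[idx]) > max_gap)
  i_end <- if (length(gaps) == 0L) idx[length(idx)] else idx[gaps[1]]
  if (length(gaps) > 0L) {
    warning("multiple activity regions found; returning the first lap")
  }
  c(t_start, rec$t[i_end])
}

#' Segment a lap into the four swimming phases
#'
#' Heuristic IMU-based segmentation: `Push.off` is where the forward
#' acceleration burst drops below `theta_push`; `Glid.off` is the first kick
#' onset, where the band power (1-4 Hz moving RMS) of the mediolateral
#' gyroscope channel exceeds `kick_ratio` times its gliding baseline (with an
#' absolute floor); `StPr.off` is the onset of the first arm-stroke cycle,
#' the first prominent positive peak of the low-passed cycle channel.
#'
#' If a reference annotation is supplied via `annotation`, it is validated and
#' returned verbatim (the camera-reference path).
#'
#' @param rec Global-frame `imu_recording` (Euler columns not required).
#' @param lap `c(t_start, t_end)` from [detect_lap_bounds()].
#' @param technique Swimming technique.
#' @param theta_push Push threshold (m/s^2).
#' @param kick_ratio Kick-power onset ratio over the gliding baseline.
#' @param kick_floor Absolute kick-power floor (rad/s RMS), default 0.3.
#' @param lp_cutoff Low-pass cutoff (Hz) isolating the stroke band, default 1.5.
#' @param min_phase Minimum phase width (s), default 0.1.
#' @param annotation Optional `phase_annotation` passthrough.
#' @return A `phase_annotation` with `source = "imu"` (or the passthrough).
#' @export
segment_phases <- function(rec, lap, technique,
                           theta_push = 1.5, kick_ratio = 5, kick_floor = 0.3,
                           lp_cutoff = 1.5, min_phase = 0.1, annotation = NULL) {
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "phase_annotation"))
    return(phase_annotation(annotation$lap, annotation$phases, annotation$source))
  }
  assert_frame(rec, "global")
  technique <- match.arg(technique, TECHNIQUES)
  fs <- imu_fs(rec)
  t0 <- lap[1]; t_end <- lap[2]
  in_lap <- rec$t >= t0 & rec$t <= t_end
  tt <- rec$t[in_lap]

  # Push.off: smoothed forward acceleration drops below threshold
  # (sustained 30 ms); smoothing removes push vibration
  ay <- lowpass(rec$acc_y, fs, 5)[in_lap]
  below <- ay < theta_push & tt > t0 + 0.05
  n_sus <- max(1L, round(0.03 * fs))
  run <- stats::filter(as.numeric(below), rep(1, n_sus), sides = 1)
  i_off <- which(!is.na(run) & run == n_sus)
  if (length(i_off) == 0L) stop("phase boundary not found: Push never ends")
  t_push_off <- tt[i_off[1] - n_sus + 1L]
  t_push_off <- max(t_push_off, t0 + min_phase)

  # Glid.off: kick onset from mediolateral gyro band power
  kick <- bandpass(rec$gyr_x[in_lap], fs, 1, 4)
  env <- moving_rms(kick, round(0.2 * fs))
  # baseline taken inside the quiet glide, after the push-off body rotation
  # (the pitch-over from upright to horizontal) has settled
  base_idx <- tt >= t_push_off + 0.4 & tt < t_push_off + 0.9
  baseline <- stats::median(env[base_idx])
  thr <- max(kick_ratio * baseline, kick_floor)
  i_kick <- which(env > thr & tt > t_push_off + 0.5)
  if (length(i_kick) == 0L) stop("phase boundary not found: no kick onset (Glid never ends)")
  t_glid_off <- max(tt[i_kick[1]], t_push_off + min_phase)

  # StPr.off: first prominent positive peak of the low-passed cycle channel
  ch <- rec[[cycle_channel(technique)]][in_lap]
  # sign-agnostic: the body-to-global axis mapping can flip the channel sign
  lp <- abs(lowpass(ch, fs, lp_cutoff))
  search <- tt > t_glid_off & tt < t_end
  seg <- lp[search]
  if (length(seg) < 10L) stop("phase boundary not found: Swim region too short")
  pk <- pracma::findpeaks(seg, minpeakheight = 0.5 * max(seg),
                          minpeakdistance = max(1L, round(0.3 * fs)))
  if (is.null(pk)) stop("phase boundary not found: no stroke cycles after kicking")
  t_swim_on <- tt[search][min(pk[, 2])]
  if (t_swim_on <= t_glid_off + min_phase) {
    warning("StPr phase collapsed to minimum width (immediate stroking)")
    t_swim_on <- t_glid_off + min_phase
  }
  if (t_swim_on >= t_end - min_phase) stop("phase boundary not found: Swim has no width")

  phase_annotation(
    lap = c(t0, t_end),
    phases = list(Push = c(t0, t_push_off),
                  Glid = c(t_push_off, t_glid_off),
                  StPr = c(t_glid_off, t_swim_on),
                  Swim = c(t_swim_on, t_end)),
    source = "imu"
  )
}

bandpass <- function(x, fs, lo, hi) {
  hi <- min(hi, 0.45 * fs)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

lowpass <- function(x, fs, cutoff) {
  bf <- signal::butter(4, min(cutoff / (fs / 2), 0.99), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

#' Separate stroke cycles within the Swim phase
#'
#' Cycle boundaries are the positive-peak times of the technique's anatomical
#' angular-velocity channel (longitudinal `gyr_y` for front crawl and
#' backstroke, mediolateral `gyr_x` for breaststroke and butterfly), after a
#' light low-pass, with a minimum peak distance of half the median inter-peak
#' interval and a relative prominence threshold.
#'
#' @param rec Anatomical-frame `imu_recording`.
#' @param swim_interval `c(on, off)` of the Swim phase (s), at least 1 s wide.
#' @param technique Swimming technique.
#' @param lp_cutoff Smoothing low-pass cutoff (Hz), default 2.5.
#' @param min_prominence Peak height floor as a fraction of the channel
#'   maximum, default 0.3.
#' @return A `cycle_set`.
#' @export
separate_cycles <- function(rec, swim_interval, technique,
                            lp_cutoff = 2.5, min_prominence = 0.3) {
  assert_frame(rec, "anatomical")
  technique <- match.arg(technique, TECHNIQUES)
  if (diff(swim_interval) < 1) stop("swim interval must be at least 1 s")
  fs <- imu_fs(rec)
  idx <- rec$t >= swim_interval[1] & rec$t < swim_interval[2]
  tt <- rec$t[idx]
  x <- lowpass(rec[[cycle_channel(technique)]][idx], fs, lp_cutoff)
  if (max(x) < 1e-6) stop("no cycles detected: cycle channel is flat")
  pk <- pracma::findpeaks(x, minpeakheight = min_prominence * max(x))
  if (is.null(pk) || nrow(pk) < 2L) stop("no cycles detected")
  ord <- sort(pk[, 2])
  # enforce minimum distance of half the median inter-peak interval
  med <- stats::median(diff(ord))
  keep <- ord[1]
  for (i in ord[-1]) if (i - keep[length(keep)] >= 0.5 * med) keep <- c(keep, i)
  if (length(keep) < 2L) stop("no cycles detected")
  cycle_set(tt[keep], technique)
}

#' Read and write phase-annotation JSON
#'
#' Format: `{"lap":[t0,t1],"phases":{"Push":[on,off],...},"source":"camera",
#' "cycles":[...]}`; `cycles` is optional.
#'
#' @param path JSON file path.
#' @param ann A `phase_annotation`.
#' @param cycles Optional `cycle_set` stored alongside.
#' @return `read_annotation_json()` returns a list with `annotation` and
#'   `cycles` (may be `NULL`).
#' @export
read_annotation_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ann <- phase_annotation(j$lap, as.list(j$phases), source = j$source)
  cyc <- NULL
  if (!is.null(j$cycles) && length(j$cycles) >= 2) {
    cyc <- cycle_set(j$cycles, technique = j$technique %||% "front_crawl")
  }
  list(annotation = ann, cycles = cyc)
}

#' @rdname read_annotation_json
#' @export
write_annotation_json <- function(ann, path, cycles = NULL) {
  obj <- list(lap = ann$lap, phases = ann$phases, source = ann$source)
  if (!is.null(cycles)) {
    obj$cycles <- cycles$boundaries
    obj$technique <- cycles$technique
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
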