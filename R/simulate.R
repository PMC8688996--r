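# Ground-truthed synthetic swimming laps.
#
# A lap scenario defines a piecewise forward-velocity model (Push rise,
# exponential Glid decay, kick-modulated StPr recovery, cyclic Swim steady
# state), an orientation trajectory (upright float -> pitch-over during the
# push -> prone/supine swimming with technique-specific roll or pitch
# oscillation), and sensor noise. The generator emits the sensor-frame IMU
# recording, the uncorrected cable-frame speedometer trace, the exact phase
# annotation, true cycle boundaries, closed-form goal metrics and the
# underlying velocity/displacement truth.

technique_defaults <- function(technique) {
  switch(technique,
    front_crawl = list(v_swim = 1.60, stroke_rate = 0.80, osc_axis = "y",
                       osc_amp = 0.78, v_mod = 0.08, v_peak = 2.60, supine = FALSE),
    breaststroke = list(v_swim = 1.15, stroke_rate = 0.60, osc_axis = "x",
                        osc_amp = 0.30, v_mod = 0.35, v_peak = 2.40, supine = FALSE),
    butterfly = list(v_swim = 1.45, stroke_rate = 0.65, osc_axis = "x",
                     osc_amp = 0.35, v_mod = 0.25, v_peak = 2.50, supine = FALSE),
    backstroke = list(v_swim = 1.40, stroke_rate = 0.75, osc_axis = "y",
                      osc_amp = 0.70, v_mod = 0.08, v_peak = 2.40, supine = TRUE),
    stop("unknown technique: ", technique)
  )
}

#' Define a synthetic lap scenario
#'
#' Defaults emulate an elite 25 m trial at full pace, sampled at 500 Hz with
#' a 100 Hz speedometer; see the technique-specific velocity, stroke-rate and
#' oscillation defaults in the methods vignette. The `pace` fraction (0.7-1)
#' scales the swimming and push-off velocities the way progressive-velocity
#' trials do.
#'
#' @param technique One of `"front_crawl"`, `"breaststroke"`, `"butterfly"`,
#'   `"backstroke"`.
#' @param pace Pace fraction in `[0.7, 1]`.
#' @param seed Integer seed; the same seed reproduces the lap bit-for-bit.
#' @param ... Overrides for any scenario field: `pool_length` (m), `fs`, `fr`
#'   (Hz), `pre_static`, `push_duration`, `glide_duration`, `stpr_duration`
#'   (s), `v_peak`, `v_swim` (m/s), `glide_k` (1/s), `kick_rate`,
#'   `stroke_rate` (Hz), `kick_amp`, `osc_amp`, `incline` (rad), `v_mod`
#'   (fraction), `noise_acc` (m/s^2), `noise_gyr` (rad/s), `noise_ref` (m/s),
#'   `parallax_h`, `parallax_d0` (m), `mount_angle` (rad), `acc_bias`,
#'   `gyr_bias`.
#' @return A list of class `lap_scenario`.
#' @export
lap_scenario <- function(technique = "front_crawl", pace = 1.0, seed = 1L, ...) {
  technique <- match.arg(technique, TECHNIQUES)
  stopifnot(pace >= 0.5, pace <= 1.1)
  td <- technique_defaults(technique)
  sc <- list(
    technique = technique, pace = pace, seed = as.integer(seed),
    pool_length = 25, fs = 500, fr = 100,
    pre_static = 5, post_quiet = 2,
    push_duration = 0.30, push_vib = 5, push_vib_freq = 10,
    glide_duration = 1.5, glide_k = 0.40,
    stpr_duration = 2.0, kick_rate = 3.0, kick_amp = 0.25,
    v_peak = td$v_peak * (0.55 + 0.45 * pace),
    v_swim = td$v_swim * pace,
    stroke_rate = td$stroke_rate * (0.80 + 0.20 * pace),
    osc_axis = td$osc_axis, osc_amp = td$osc_amp, v_mod = td$v_mod,
    supine = td$supine,
    incline = 0.10, sway_acc = 0.6, heave_acc = 0.4,
    noise_acc = 0.05, noise_gyr = 0.01, noise_ref = 0.005,
    parallax_h = 0.62, parallax_d0 = 0.30,
    mount_angle = 0.20, mount_axis = c(0, 0, 1),
    acc_bias = c(0.02, -0.01, 0.03), gyr_bias = c(0.002, -0.001, 0.001)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown)) stop("unknown scenario field(s): ", paste(unknown, collapse = ", "))
  sc[names(dots)] <- dots
  if (any(unlist(sc[c("push_duration", "glide_duration", "stpr_duration")]) <= 0)) {
    stop("phase durations must be positive")
  }
  if (sc$v_peak <= sc$v_swim * 0.8) stop("push peak velocity implausibly low")
  structure(sc, class = "lap_scenario")
}

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x^2 * (3 - 2 * x)
}

# piecewise forward-velocity model; returns v(t) evaluated on t (vectorized)
scenario_velocity <- function(sc, t, t_end) {
  t0 <- sc$pre_static
  t1 <- t0 + sc$push_duration
  t2 <- t1 + sc$glide_duration
  t3 <- t2 + sc$stpr_duration
  v_ge <- sc$v_peak * exp(-sc$glide_k * sc$glide_duration)
  v <- numeric(length(t))
  i <- t >= t0 & t < t1
  x <- (t[i] - t0) / sc$push_duration
  # leg-drive vibration: band-limited ripple with acceleration amplitude
  # push_vib (m/s^2), windowed to vanish at both push boundaries so the
  # glide entry velocity stays exactly v_peak
  wind <- smoothstep((x - 0.25) / 0.15) * (1 - smoothstep((x - 0.8) / 0.15))
  v[i] <- sc$v_peak * sin(pi / 2 * x) +
    sc$push_vib / (2 * pi * sc$push_vib_freq) *
      sin(2 * pi * sc$push_vib_freq * x * sc$push_duration) * wind
  i <- t >= t1 & t < t2
  v[i] <- sc$v_peak * exp(-sc$glide_k * (t[i] - t1))
  i <- t >= t2 & t < t3
  s <- smoothstep((t[i] - t2) / sc$stpr_duration)
  ripple <- 0.05 * sc$v_swim * sin(2 * pi * sc$kick_rate * (t[i] - t2)) *
    4 * s * (1 - s)
  v[i] <- v_ge + (sc$v_swim - v_ge) * s + ripple
  i <- t >= t3 & t <= t_end
  v[i] <- sc$v_swim * (1 + sc$v_mod * sin(2 * pi * sc$stroke_rate * (t[i] - t3)))
  i <- t > t_end
  if (any(i)) {
    v[i] <- sc$v_swim * (1 + sc$v_mod * sin(2 * pi * sc$stroke_rate * (t_end - t3))) *
      exp(-20 * (t[i] - t_end))
  }
  v
}

# times at which the displacement reaches pool_length (the wall touch)
scenario_t_end <- function(sc) {
  # integrate on a fine fixed grid, then interpolate the crossing
  dt <- 1 / sc$fs
  t <- seq(0, sc$pre_static + 60, by = dt)
  v <- scenario_velocity(sc, t, t_end = Inf)
  d <- pracma::cumtrapz(t, v)[, 1]
  if (max(d) < sc$pool_length) stop("scenario never reaches the pool length")
  first_crossing(t, d, sc$pool_length)
}

quat_about <- function(axis_char, angle) {
  # vectorized single-axis quaternion
  c0 <- cos(angle / 2); s0 <- sin(angle / 2)
  z <- numeric(length(angle))
  switch(axis_char,
         x = cbind(c0, s0, z, z),
         y = cbind(c0, z, s0, z),
         z = cbind(c0, z, z, s0))
}

# body angular velocity from a quaternion sequence (central differences)
gyro_from_quat <- function(q, dt) {
  n <- nrow(q)
  qdot <- (q[c(2:n, n), ] - q[c(1, 1:(n - 1)), ]) /
    (c(dt, rep(2 * dt, n - 2), dt))
  w <- 2 * quat_multiply(quat_conjugate(q), qdot)
  quat_as_matrix(w)[, 2:4, drop = FALSE]
}

#' Simulate one ground-truthed swimming lap
#'
#' @param sc A [lap_scenario()].
#' @return A list of class `swim_lap` with elements `imu_sensor` (sensor-frame
#'   `imu_recording`), `calibration` (`calibration_params` that undo the
#'   simulated mounting/bias), `reference` (uncorrected cable-frame
#'   `reference_trace`), `annotation` (exact `phase_annotation`,
#'   source `"synthetic"`), `cycles_true` (`cycle_set`), `goals_true`
#'   (`goal_metric_set` from the closed-form velocity model), `truth`
#'   (tibble `t`, `v`, `d`, plus the true quaternion columns), and `scenario`.
#' @export
simulate_lap <- function(sc) {
  stopifnot(inherits(sc, "lap_scenario"))
  set.seed(sc$seed)
  fs <- sc$fs; dt <- 1 / fs
  t0 <- sc$pre_static
  t1 <- t0 + sc$push_duration
  t2 <- t1 + sc$glide_duration
  t3 <- t2 + sc$stpr_duration
  t_end <- scenario_t_end(sc)
  if (t_end <= t3 + 1.5) stop("scenario leaves less than 1.5 s of Swim phase")
  t <- seq(0, t_end + sc$post_quiet, by = dt)
  n <- length(t)

  # --- forward kinematics truth ---
  v <- scenario_velocity(sc, t, t_end)
  d <- pracma::cumtrapz(t, v)[, 1]
  acc_fwd <- pracma::gradient(v, dt)

  # --- orientation truth ---
  q_up <- if (sc$supine) c(sqrt(0.5), sqrt(0.5), 0, 0) else c(0, 0, sqrt(0.5), sqrt(0.5))
  q_base_end <- if (sc$supine) c(1, 0, 0, 0) else c(0, 0, 1, 0)
  q_swim <- quat_multiply(q_base_end, quat_from_axis_angle(c(1, 0, 0), sc$incline))
  s_tr <- smoothstep((t - t0) / (sc$push_duration + 0.1))
  q_base <- quat_slerp(q_up, q_swim, s_tr)

  ramp <- function(tt, on, off, r_on = 0.1, r_off = 0.2) {
    smoothstep((tt - on) / r_on) * (1 - smoothstep((tt - off) / r_off))
  }
  a_kick <- sc$kick_amp * sin(2 * pi * sc$kick_rate * (t - t2)) * ramp(t, t2, t3)
  a_stroke <- sc$osc_amp * sin(2 * pi * sc$stroke_rate * (t - t3)) *
    ramp(t, t3, t_end, r_off = 0.1)
  q_osc <- quat_multiply(quat_about("x", a_kick), quat_about(sc$osc_axis, a_stroke))
  q_true <- quat_normalize(quat_multiply(q_base, q_osc))

  # --- global accelerations ---
  in_swim <- smoothstep((t - t3) / 0.2) * (1 - smoothstep((t - t_end) / 0.2))
  in_stpr <- ramp(t, t2, t3)
  acc_x <- sc$sway_acc * in_swim * sin(2 * pi * sc$stroke_rate * (t - t3) + pi / 2)
  acc_z <- sc$heave_acc * in_swim * sin(2 * pi * 2 * sc$stroke_rate * (t - t3)) +
    0.3 * in_stpr * sin(2 * pi * sc$kick_rate * (t - t2))
  acc_g <- cbind(acc_x, acc_fwd, acc_z)

  # --- map to anatomical sensor signals ---
  q_conj <- quat_conjugate(q_true)
  acc_spec <- acc_g
  acc_spec[, 3] <- acc_spec[, 3] + GRAVITY
  acc_a <- quat_rotate(q_conj, acc_spec)
  gyr_a <- gyro_from_quat(q_true, dt)

  # --- anatomical -> sensor: mounting rotation, scale identity, bias, noise ---
  r_mount <- quat_to_matrix(quat_from_axis_angle(sc$mount_axis, sc$mount_angle))
  # calibration maps sensor -> anatomical with R = r_mount; invert it here
  acc_s <- acc_a %*% r_mount # (R^T v)^T rows = v^T R
  gyr_s <- gyr_a %*% r_mount
  acc_s <- sweep(acc_s, 2, -sc$acc_bias) +
    matrix(stats::rnorm(3 * n, 0, sc$noise_acc), n, 3)
  gyr_s <- sweep(gyr_s, 2, -sc$gyr_bias) +
    matrix(stats::rnorm(3 * n, 0, sc$noise_gyr), n, 3)
  imu_sensor <- imu_recording(t, acc_s, gyr_s, fs = fs, frame = "sensor")
  cal <- calibration_params(acc_bias = sc$acc_bias, gyr_bias = sc$gyr_bias,
                            r_sensor_to_anatomical = r_mount)

  # --- reference trace: cable-frame speedometer with parallax ---
  tr_t <- seq(0, max(t), by = 1 / sc$fr)
  v_r <- stats::approx(t, v, xout = tr_t)$y
  d_r <- stats::approx(t, d, xout = tr_t)$y
  x_pos <- sc$parallax_d0 + d_r
  ell <- sqrt(x_pos^2 + sc$parallax_h^2)
  v_cable <- v_r * x_pos / ell
  d_cable <- ell - ell[1]
  v_cable <- v_cable + stats::rnorm(length(tr_t), 0, sc$noise_ref)
  reference <- reference_trace(tr_t, v_cable, d_cable, fr = sc$fr,
                               corrected = FALSE)

  # --- truth objects ---
  annotation <- phase_annotation(
    lap = c(t0, t_end),
    phases = list(Push = c(t0, t1), Glid = c(t1, t2),
                  StPr = c(t2, t3), Swim = c(t3, t_end)),
    source = "synthetic")
  cyc_b <- seq(t3, t_end, by = 1 / sc$stroke_rate)
  cycles_true <- cycle_set(cyc_b, sc$technique)
  goals_true <- true_goal_metrics(sc, t, v, d, annotation, cycles_true)

  truth <- tibble::tibble(t = t, v = v, d = d,
                          q1 = q_true[, 1], q2 = q_true[, 2],
                          q3 = q_true[, 3], q4 = q_true[, 4])
  structure(list(imu_sensor = imu_sensor, calibration = cal,
                 reference = reference, annotation = annotation,
                 cycles_true = cycles_true, goals_true = goals_true,
                 truth = truth, scenario = sc),
            class = "swim_lap")
}

true_goal_metrics <- function(sc, t, v, d, annotation, cycles) {
  lap <- annotation$lap
  ci <- cycle_intervals(cycles)
  tv <- function(iv) {
    i <- t >= iv[1] & t < iv[2]
    pracma::trapz(t[i], v[i]) / (t[i][sum(i)] - t[i][1])
  }
  out <- tibble::tibble(
    push_vmax = sc$v_peak,
    glid_vend = sc$v_peak * exp(-sc$glide_k * sc$glide_duration),
    stpr_vavg = tv(annotation$phases$StPr),
    swim_vavg_phase = tv(annotation$phases$Swim),
    t5m = first_crossing(t, d - stats::approx(t, d, lap[1])$y, 5) - lap[1],
    t15m = first_crossing(t, d - stats::approx(t, d, lap[1])$y, 15) - lap[1],
    lap_vavg = sc$pool_length / (lap[2] - lap[1]),
    swim_vavg_cycle = list(tibble::tibble(
      cycle = ci$cycle,
      v_avg = vapply(seq_len(nrow(ci)), function(k) tv(c(ci$on[k], ci$off[k])),
                     numeric(1))))
  )
  class(out) <- c("goal_metric_set", class(out))
  out
}

#' Simulate a cohort of swimmers with latent ability
#'
#' Each swimmer draws a latent ability `alpha ~ N(0, ability_sd^2)` that
#' modulates swimming velocity, push-off strength, glide drag, stroke and
#' kick rates and posture (better swimmers are faster, glide flatter and
#' lose less speed); each of the four progressive paces (0.7, 0.8, 0.9, 1.0)
#' yields one trial per technique, with small per-trial jitter.
#'
#' @param n_swimmers Number of swimmers, default 19.
#' @param techniques Character vector of techniques, default `"front_crawl"`.
#' @param paces Pace fractions, default `c(0.7, 0.8, 0.9, 1.0)`.
#' @param ability_sd SD of the latent ability, default 1.
#' @param jitter_sd Relative per-trial jitter SD, default 0.015.
#' @param seed Integer seed.
#' @param ... Further overrides passed to every [lap_scenario()].
#' @return A list of class `swim_cohort` with `laps` (list of `swim_lap`),
#'   `meta` (tibble `lap_id`, `swimmer`, `technique`, `pace`, `trial`) and
#'   `swimmers` (latent ability table).
#' @export
simulate_cohort <- function(n_swimmers = 19, techniques = "front_crawl",
                            paces = c(0.7, 0.8, 0.9, 1.0), ability_sd = 1,
                            jitter_sd = 0.015, seed = 1L, ...) {
  stopifnot(n_swimmers >= 2)
  set.seed(seed)
  alpha <- stats::rnorm(n_swimmers, 0, ability_sd)
  swimmers <- tibble::tibble(swimmer = seq_len(n_swimmers), ability = alpha)
  laps <- list()
  meta <- list()
  lap_id <- 0L
  for (s in seq_len(n_swimmers)) {
    a <- alpha[s]
    for (tech in techniques) {
      td <- technique_defaults(tech)
      for (k in seq_along(paces)) {
        p <- paces[k]
        lap_id <- lap_id + 1L
        jit <- function() 1 + stats::rnorm(1, 0, jitter_sd)
        sc <- lap_scenario(
          technique = tech, pace = p,
          seed = (sc_seed <- (seed + 7919L * lap_id) %% 2147483647L),
          v_swim = td$v_swim * p * (1 + 0.06 * a) * jit(),
          v_peak = td$v_peak * (0.55 + 0.45 * p) * (1 + 0.05 * a) * jit(),
          glide_k = 0.40 * (1 - 0.10 * a) * jit(),
          glide_duration = 1.5 * (1.15 - 0.15 * p) * jit(),
          stpr_duration = 2.0 * (1.1 - 0.1 * p) * jit(),
          kick_rate = 3.0 * (0.85 + 0.15 * p) * (1 + 0.03 * a) * jit(),
          stroke_rate = td$stroke_rate * (0.80 + 0.20 * p) * (1 + 0.04 * a) * jit(),
          incline = max(0.03, 0.10 - 0.02 * a + stats::rnorm(1, 0, 0.01)),
          osc_amp = td$osc_amp * jit(),
          v_mod = td$v_mod * jit(),
          ...
        )
        laps[[lap_id]] <- simulate_lap(sc)
        meta[[lap_id]] <- tibble::tibble(
          lap_id = lap_id, swimmer = s, technique = tech, pace = p, trial = k)
      }
    }
  }
  structure(list(laps = laps, meta = dplyr::bind_rows(meta), swimmers = swimmers),
            class = "swim_cohort")
}

#' Simulate a planted feature-to-goal regression dataset
#'
#' `X` is standard normal (optionally with a correlated block to exercise the
#' VIF filter); `y = X beta + eps` with `beta` supported on the first
#' `support_size` columns.
#'
#' @param n Observations.
#' @param p Predictors.
#' @param support_size Number of truly active predictors.
#' @param coefs Coefficient value(s) for the active predictors (recycled).
#' @param noise_sd SD of the additive noise.
#' @param seed Integer seed.
#' @param cor_block Optional integer: adds `cor_block` extra columns that are
#'   near-copies (noise SD 0.01) of the first column, appended at the end.
#' @return A list with `x` (tibble `v1..vp`), `y`, `support` (names),
#'   `beta`.
#' @export
simulate_feature_goal_dataset <- function(n, p, support_size, coefs = 1,
                                          noise_sd = 1, seed = 1L,
                                          cor_block = 0) {
  stopifnot(support_size <= p)
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p)
  if (cor_block > 0) {
    extra <- x[, rep(1, cor_block), drop = FALSE] +
      matrix(stats::rnorm(n * cor_block, 0, 0.01), n, cor_block)
    x <- cbind(x, extra)
  }
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  beta <- numeric(ncol(x))
  beta[seq_len(support_size)] <- rep_len(coefs, support_size)
  y <- as.numeric(x %*% beta) + stats::rnorm(n, 0, noise_sd)
  list(x = tibble::as_tibble(as.data.frame(x)), y = y,
       support = paste0("v", seq_len(support_size)), beta = beta)
}
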