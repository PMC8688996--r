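# Sensor-to-global IMU data preparation.
#
# Frames: sensor -> anatomical (x mediolateral, y longitudinal/cranial,
# z anterior-posterior) -> global (X lateral, Y swimming direction,
# Z vertical up). Gravity is +9.81 m/s^2 on the global Z accelerometer
# channel when static (specific force convention).

GRAVITY <- 9.81

#' Apply intrinsic and anatomical calibration
#'
#' Per sample and per sensor, `v <- R %*% S %*% (v - bias)` where `S` is the
#' scale/non-orthogonality matrix and `R` the sensor-to-anatomical rotation.
#'
#' @param raw An `imu_recording` in the `sensor` frame.
#' @param cal A [calibration_params()] object.
#' @return An `imu_recording` in the `anatomical` frame.
#' @export
apply_calibration <- function(raw, cal) {
  assert_frame(raw, "sensor")
  if (!inherits(cal, "calibration_params")) stop("cal must be calibration_params")
  r <- cal$r_sensor_to_anatomical
  acc <- sweep(imu_acc(raw), 2, cal$acc_bias) %*% t(cal$acc_scale) %*% t(r)
  gyr <- sweep(imu_gyr(raw), 2, cal$gyr_bias) %*% t(cal$gyr_scale) %*% t(r)
  imu_recording(raw$t, acc, gyr, fs = imu_fs(raw), frame = "anatomical")
}

#' Invert a calibration (utility for round-trip checks)
#'
#' @param cal A `calibration_params` object.
#' @return A function mapping an anatomical recording back to the sensor frame.
#' @keywords internal
uncalibrate <- function(cal) {
  function(rec) {
    assert_frame(rec, "anatomical")
    r <- cal$r_sensor_to_anatomical
    acc <- sweep(imu_acc(rec) %*% r %*% t(solve(cal$acc_scale)), 2, -cal$acc_bias)
    gyr <- sweep(imu_gyr(rec) %*% r %*% t(solve(cal$gyr_scale)), 2, -cal$gyr_bias)
    imu_recording(rec$t, acc, gyr, fs = imu_fs(rec), frame = "sensor")
  }
}

#' Estimate the sensor-to-anatomical alignment from functional movements
#'
#' The longitudinal (cranial-positive) axis is the mean gravity reaction
#' direction while standing upright; the mediolateral axis is the dominant
#' rotation axis during squats (pelvis flexion-extension), orthogonalized
#' against the longitudinal axis, with its sign fixed so that the first squat
#' movement (anterior pelvic tilt on descent) is a positive rotation; the
#' anterior-posterior axis completes the right-handed triad (z = x cross y).
#'
#' @param standing Sensor-frame recording of >= 2 s quiet upright standing.
#' @param squats Sensor-frame recording containing >= 2 squat repetitions.
#' @return A 3 x 3 rotation matrix mapping sensor axes to anatomical axes.
#' @export
estimate_functional_alignment <- function(standing, squats) {
  assert_frame(standing, "sensor")
  assert_frame(squats, "sensor")
  if (max(standing$t) - min(standing$t) < 2 - 1e-9) {
    stop("standing window must cover at least 2 s")
  }
  a_mean <- colMeans(imu_acc(standing))
  g_norm <- sqrt(sum(a_mean^2))
  if (g_norm < 9.3 || g_norm > 10.3) {
    stop(sprintf("standing window is not static: gravity norm %.2f m/s^2 outside [9.3, 10.3]",
                 g_norm))
  }
  y_axis <- a_mean / g_norm

  w <- imu_gyr(squats)
  # dominant rotation axis: principal eigenvector of the gyro second moment
  ev <- eigen(crossprod(w) / nrow(w), symmetric = TRUE)
  x_axis <- ev$vectors[, 1]
  ang <- acos(min(1, abs(sum(x_axis * y_axis))))
  if (ang < 10 * pi / 180) {
    stop("squat rotation axis within 10 degrees of the longitudinal axis; cannot align")
  }
  x_axis <- x_axis - sum(x_axis * y_axis) * y_axis
  x_axis <- x_axis / sqrt(sum(x_axis^2))
  # sign: anterior tilt at squat onset is a positive rotation about +x
  n_on <- max(2L, floor(nrow(w) / 4))
  if (sum(w[seq_len(n_on), ] %*% x_axis) < 0) x_axis <- -x_axis
  z_axis <- c(
    x_axis[2] * y_axis[3] - x_axis[3] * y_axis[2],
    x_axis[3] * y_axis[1] - x_axis[1] * y_axis[3],
    x_axis[1] * y_axis[2] - x_axis[2] * y_axis[1]
  )
  rbind(x_axis, y_axis, z_axis, deparse.level = 0)
}

#' Estimate the initial orientation from a quasi-static upright window
#'
#' Returns the smallest rotation aligning the window-mean accelerometer
#' direction with the global vertical; yaw about the vertical is zero by
#' definition (the pool's swimming direction is fixed later from the push-off
#' burst, see [prepare_imu()]).
#'
#' @param static An anatomical-frame recording of about 5 s of upright
#'   floating before the lap.
#' @param gyro_rms_warn Warn if the gyro RMS exceeds this (rad/s).
#' @return A unit quaternion.
#' @export
estimate_initial_orientation <- function(static, gyro_rms_warn = 0.2) {
  assert_frame(static, "anatomical")
  w <- imu_gyr(static)
  if (sqrt(mean(w^2)) > gyro_rms_warn) {
    warning("initial-orientation window is not static (gyro RMS above threshold); using the mean anyway")
  }
  a <- colMeans(imu_acc(static))
  a <- a / sqrt(sum(a^2))
  z <- c(0, 0, 1)
  axis <- c(a[2] * z[3] - a[3] * z[2],
            a[3] * z[1] - a[1] * z[3],
            a[1] * z[2] - a[2] * z[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-9) {
    if (sum(a * z) > 0) return(c(1, 0, 0, 0))
    return(c(0, 1, 0, 0)) # upside down: 180 deg about X
  }
  quat_from_axis_angle(axis, atan2(s, sum(a * z)))
}

#' Fuse gyroscope and accelerometer into an orientation trace
#'
#' Gradient-descent complementary filter (IMU variant, no magnetometer):
#' the quaternion is propagated by gyroscope integration and corrected each
#' sample by a normalized gradient step on the objective that aligns the
#' quaternion's predicted gravity direction with the measured (normalized)
#' accelerometer vector. The correction cannot observe yaw, which therefore
#' follows the gyroscope alone.
#'
#' The accelerometer only measures gravity when the body is not accelerating,
#' so the correction is gated: samples whose specific-force norm deviates
#' from 9.81 m/s^2 by more than `acc_gate` (wall push-off, strong propulsion)
#' propagate by the gyroscope alone.
#'
#' @param rec An anatomical-frame `imu_recording`.
#' @param q0 Initial unit quaternion (e.g. [estimate_initial_orientation()]).
#' @param gain Filter gain beta (1/s); default 0.1.
#' @param acc_gate Gate width (m/s^2); default 2. `Inf` disables gating.
#' @return An `orientation_trace`: tibble with `t`, `q1..q4` and Euler angles
#'   `psi`, `theta`, `phi` (radians, unwrapped along time).
#' @export
fuse_orientation <- function(rec, q0 = c(1, 0, 0, 0), gain = 0.1, acc_gate = 2) {
  assert_frame(rec, "anatomical")
  if (nrow(rec) == 0L) stop("empty recording")
  if (anyNA(rec)) stop("recording contains NA samples")
  if (!is.numeric(gain) || gain <= 0) stop("gain must be positive")
  dt <- 1 / imu_fs(rec)
  n <- nrow(rec)
  acc <- imu_acc(rec); gyr <- imu_gyr(rec)
  q <- matrix(0, n, 4)
  q1 <- q0[1]; q2 <- q0[2]; q3 <- q0[3]; q4 <- q0[4]
  nrm <- sqrt(q1^2 + q2^2 + q3^2 + q4^2)
  q1 <- q1 / nrm; q2 <- q2 / nrm; q3 <- q3 / nrm; q4 <- q4 / nrm
  for (i in seq_len(n)) {
    wx <- gyr[i, 1]; wy <- gyr[i, 2]; wz <- gyr[i, 3]
    # quaternion derivative from gyro: 0.5 * q (x) (0, w)
    d1 <- 0.5 * (-q2 * wx - q3 * wy - q4 * wz)
    d2 <- 0.5 * (q1 * wx + q3 * wz - q4 * wy)
    d3 <- 0.5 * (q1 * wy - q2 * wz + q4 * wx)
    d4 <- 0.5 * (q1 * wz + q2 * wy - q3 * wx)
    ax <- acc[i, 1]; ay <- acc[i, 2]; az <- acc[i, 3]
    an <- sqrt(ax^2 + ay^2 + az^2)
    if (an > 1e-6 && abs(an - GRAVITY) <= acc_gate) {
      ax <- ax / an; ay <- ay / an; az <- az / an
      # objective: predicted body-frame gravity (row 3 of R) minus measurement
      f1 <- 2 * (q2 * q4 - q1 * q3) - ax
      f2 <- 2 * (q3 * q4 + q1 * q2) - ay
      f3 <- 1 - 2 * (q2^2 + q3^2) - az
      g1 <- -2 * q3 * f1 + 2 * q2 * f2
      g2 <- 2 * q4 * f1 + 2 * q1 * f2 - 4 * q2 * f3
      g3 <- -2 * q1 * f1 + 2 * q4 * f2 - 4 * q3 * f3
      g4 <- 2 * q2 * f1 + 2 * q3 * f2
      gn <- sqrt(g1^2 + g2^2 + g3^2 + g4^2)
      if (gn > 1e-12) {
        d1 <- d1 - gain * g1 / gn
        d2 <- d2 - gain * g2 / gn
        d3 <- d3 - gain * g3 / gn
        d4 <- d4 - gain * g4 / gn
      }
    }
    q1 <- q1 + d1 * dt; q2 <- q2 + d2 * dt; q3 <- q3 + d3 * dt; q4 <- q4 + d4 * dt
    nrm <- sqrt(q1^2 + q2^2 + q3^2 + q4^2)
    q1 <- q1 / nrm; q2 <- q2 / nrm; q3 <- q3 / nrm; q4 <- q4 / nrm
    q[i, 1] <- q1; q[i, 2] <- q2; q[i, 3] <- q3; q[i, 4] <- q4
  }
  orientation_trace(rec$t, q)
}

#' Build an orientation trace from times and quaternions
#'
#' @param t Time vector (s).
#' @param q n x 4 matrix of unit quaternions.
#' @return A tibble of class `orientation_trace` with Euler angle columns
#'   (radians, unwrapped along time so phase statistics are continuous).
#' @export
orientation_trace <- function(t, q) {
  q <- quat_as_matrix(q)
  stopifnot(length(t) == nrow(q))
  eul <- quaternion_to_euler(q)
  out <- tibble::tibble(
    t = as.numeric(t), q1 = q[, 1], q2 = q[, 2], q3 = q[, 3], q4 = q[, 4],
    psi = unwrap_angle(eul$psi),
    theta = unwrap_angle(eul$theta),
    phi = unwrap_angle(eul$phi)
  )
  structure(out, class = c("orientation_trace", class(tibble::tibble())))
}

unwrap_angle <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  corr <- cumsum(round(d / (2 * pi)))
  x - c(0, corr * 2 * pi)
}

trace_quat <- function(trace) cbind(trace$q1, trace$q2, trace$q3, trace$q4)

#' Rotate an anatomical recording into the global frame
#'
#' Applies the quaternion sandwich product per sample to the accelerometer
#' and gyroscope vectors, then subtracts gravity (9.81 m/s^2) from the global
#' vertical acceleration channel so that all three channels are motion
#' accelerations.
#'
#' @param rec An anatomical-frame `imu_recording`.
#' @param trace An `orientation_trace` of matching length.
#' @return A global-frame `imu_recording` carrying the Euler angle columns
#'   `psi`, `theta`, `phi` from the trace.
#' @export
rotate_to_global <- function(rec, trace) {
  assert_frame(rec, "anatomical")
  if (nrow(rec) != nrow(trace)) stop("recording and orientation trace lengths differ")
  q <- trace_quat(trace)
  acc <- quat_rotate(q, imu_acc(rec))
  acc[, 3] <- acc[, 3] - GRAVITY
  gyr <- quat_rotate(q, imu_gyr(rec))
  out <- imu_recording(rec$t, acc, gyr, fs = imu_fs(rec), frame = "global")
  out$psi <- trace$psi; out$theta <- trace$theta; out$phi <- trace$phi
  out
}

#' Prepare a raw lap recording: calibrate, fuse, rotate to global
#'
#' Runs the full data-preparation chain: [apply_calibration()],
#' [estimate_initial_orientation()] on the pre-lap static window,
#' [fuse_orientation()] and [rotate_to_global()]. Because the initial
#' orientation fixes yaw only up to the unknown facing direction, the global
#' Y axis is then anchored to the swimming direction: if the integrated
#' forward acceleration over the push-off burst is negative, the global frame
#' is rotated 180 degrees about Z.
#'
#' @param raw Sensor-frame `imu_recording` covering static float + lap.
#' @param cal `calibration_params`.
#' @param static_window `c(t0, t1)` of the upright static float (default the
#'   first 5 s).
#' @param gain Fusion gain (1/s).
#' @return A list with `global` (global-frame recording with Euler columns),
#'   `anatomical`, `trace` and `q0`.
#' @export
prepare_imu <- function(raw, cal = calibration_params(),
                        static_window = NULL, gain = 0.1) {
  rec_a <- apply_calibration(raw, cal)
  if (is.null(static_window)) static_window <- c(rec_a$t[1], rec_a$t[1] + 5)
  idx <- rec_a$t >= static_window[1] & rec_a$t < static_window[2]
  if (!any(idx)) stop("static window contains no samples")
  q0 <- estimate_initial_orientation(new_imu_recording(
    rec_a[idx, ], fs = imu_fs(rec_a), frame = "anatomical"))
  trace <- fuse_orientation(rec_a, q0 = q0, gain = gain)
  glob <- rotate_to_global(rec_a, trace)
  # anchor global +Y to the swimming direction via the push-off burst
  burst <- which(abs(glob$acc_y) > 3)
  if (length(burst) > 0) {
    i0 <- burst[1]
    i1 <- min(nrow(glob), i0 + round(0.5 * imu_fs(glob)))
    if (sum(glob$acc_y[i0:i1]) < 0) {
      qz <- c(0, 0, 0, 1) # 180 deg about global Z
      trace <- orientation_trace(trace$t, quat_multiply(
        matrix(qz, nrow = 1)[rep(1, nrow(trace)), ], trace_quat(trace)))
      glob <- rotate_to_global(rec_a, trace)
    }
  }
  list(global = glob, anatomical = rec_a, trace = trace, q0 = q0)
}
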