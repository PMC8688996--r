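test_that("apply_calibration handles identity, bias and rotation cases", {
  rec <- static_recording(gdir = c(0, 0, 1), dur = 1, frame = "sensor")
  out <- apply_calibration(rec, calibration_params())
  expect_identical(imu_frame(out), "anatomical")
  expect_equal(out$acc_z, rec$acc_z, tolerance = 1e-12)

  cal_b <- calibration_params(acc_bias = c(0, 0, 9.81))
  out_b <- apply_calibration(rec, cal_b)
  expect_equal(max(abs(cbind(out_b$acc_x, out_b$acc_y, out_b$acc_z))), 0,
               tolerance = 1e-12)

  # 90 degrees about z maps (1,0,0) like the explicit rotation matrix does
  r_z <- quat_to_matrix(quat_from_axis_angle(c(0, 0, 1), pi / 2))
  rec_x <- imu_recording(0, matrix(c(1, 0, 0), 1), matrix(0, 1, 3),
                         fs = 500, frame = "sensor")
  out_r <- apply_calibration(rec_x, calibration_params(r_sensor_to_anatomical = r_z))
  expect_equal(c(out_r$acc_x, out_r$acc_y, out_r$acc_z),
               drop(r_z %*% c(1, 0, 0)), tolerance = 1e-12)

  expect_error(calibration_params(acc_scale = matrix(0, 3, 3)), "invertible")
  expect_error(calibration_params(r_sensor_to_anatomical = diag(c(1, 1, 2))),
               "rotation")
})

test_that("calibration round-trips through its inverse", {
  set.seed(5)
  cal <- calibration_params(
    acc_bias = rnorm(3, 0, 0.1), gyr_bias = rnorm(3, 0, 0.01),
    acc_scale = diag(3) + matrix(rnorm(9, 0, 0.02), 3, 3),
    r_sensor_to_anatomical = quat_to_matrix(quat_normalize(rnorm(4)))
  )
  rec <- static_recording(dur = 0.5, noise_acc = 0.5, noise_gyr = 0.2,
                          frame = "sensor")
  back <- swimphase:::uncalibrate(cal)(apply_calibration(rec, cal))
  expect_equal(as.matrix(back[-1]), as.matrix(rec[-1]), tolerance = 1e-10)
})

simulate_calibration_windows <- function(r_mount, noise = 0, seed = 1) {
  set.seed(seed)
  fs <- 200
  # standing: anatomical gravity along +y (cranial)
  t_s <- seq(0, 2.5, by = 1 / fs)
  acc_a <- matrix(rep(c(0, 9.81, 0), each = length(t_s)), ncol = 3)
  # squats: anterior tilt first, 3 repetitions at 0.5 Hz about anatomical x
  t_q <- seq(0, 6, by = 1 / fs)
  ang <- 0.5 * (1 - cos(2 * pi * 0.5 * t_q)) / 2
  gyr_a <- cbind(0.5 * pi * 0.5 * sin(2 * pi * 0.5 * t_q), 0, 0)
  acc_q <- t(vapply(ang, function(a) {
    quat_rotate(quat_conjugate(quat_from_axis_angle(c(1, 0, 0), a)), c(0, 9.81, 0))
  }, numeric(3)))
  to_sensor <- function(m) m %*% r_mount # rows v^T R = (R^T v)^T
  n_s <- length(t_s); n_q <- length(t_q)
  standing <- imu_recording(
    t_s, to_sensor(acc_a) + matrix(rnorm(3 * n_s, 0, noise), n_s, 3),
    matrix(rnorm(3 * n_s, 0, noise / 10), n_s, 3), fs = fs, frame = "sensor")
  squats <- imu_recording(
    t_q, to_sensor(acc_q) + matrix(rnorm(3 * n_q, 0, noise), n_q, 3),
    to_sensor(gyr_a) + matrix(rnorm(3 * n_q, 0, noise / 10), n_q, 3),
    fs = fs, frame = "sensor")
  list(standing = standing, squats = squats)
}

test_that("functional alignment recovers the mounting rotation", {
  # sensor already anatomical -> identity
  w <- simulate_calibration_windows(diag(3))
  r <- estimate_functional_alignment(w$standing, w$squats)
  expect_lt(max(abs(r - diag(3))), 1e-6)
  # mounted 30 degrees about the mediolateral axis -> inverted within 2 deg
  r_mount <- quat_to_matrix(quat_from_axis_angle(c(1, 0, 0), pi / 6))
  w2 <- simulate_calibration_windows(r_mount)
  r2 <- estimate_functional_alignment(w2$standing, w2$squats)
  resid <- r2 %*% t(r_mount) # should be the identity
  ang_err <- acos(pmin(1, (sum(diag(resid)) - 1) / 2)) * 180 / pi
  expect_lt(ang_err, 2)
})

test_that("functional alignment tolerates sensor noise", {
  set.seed(20)
  r_mount <- quat_to_matrix(quat_from_axis_angle(c(0.3, 0.1, 1), 0.4))
  errs <- vapply(1:25, function(s) {
    w <- simulate_calibration_windows(r_mount, noise = 0.05, seed = s)
    r <- estimate_functional_alignment(w$standing, w$squats)
    resid <- r %*% t(r_mount)
    acos(pmin(1, (sum(diag(resid)) - 1) / 2)) * 180 / pi
  }, numeric(1))
  expect_lt(max(errs), 2)
})

test_that("functional alignment rejects bad windows", {
  w <- simulate_calibration_windows(diag(3))
  moving <- w$standing
  moving$acc_y <- moving$acc_y * 2 # gravity norm far off
  expect_error(estimate_functional_alignment(moving, w$squats), "not static")
  degenerate <- w$squats
  degenerate$gyr_x <- 0
  degenerate$gyr_y <- 1 # rotation about the longitudinal axis
  expect_error(estimate_functional_alignment(w$standing, degenerate),
               "longitudinal")
})

test_that("initial orientation aligns mean gravity with the global vertical", {
  # gravity along the designated upright axis -> the estimated quaternion
  # sends the measured direction to vertical
  rec <- static_recording(gdir = c(0, 1, 0), dur = 5)
  q <- estimate_initial_orientation(rec)
  expect_lt(max(abs(quat_rotate(q, c(0, 1, 0)) - c(0, 0, 1))), 1e-9)

  # 20-degree forward tilt reads back as 20 +- 0.5 degrees
  tilt <- quat_from_axis_angle(c(1, 0, 0), 20 * pi / 180)
  gdir <- quat_rotate(quat_conjugate(tilt), c(0, 0, 1))
  rec_t <- static_recording(gdir = gdir, dur = 5)
  q_t <- estimate_initial_orientation(rec_t)
  expect_lt(quat_angle(q_t, tilt) * 180 / pi, 0.5)
  expect_equal(quat_angle(q_t, c(1, 0, 0, 0)) * 180 / pi, 20, tolerance = 0.5)
  expect_lt(max(abs(quat_rotate(q_t, gdir) - c(0, 0, 1))), 1e-6)
})

test_that("initial orientation is robust to accelerometer noise", {
  tilt <- quat_from_axis_angle(c(1, 0, 0), 20 * pi / 180)
  gdir <- quat_rotate(quat_conjugate(tilt), c(0, 0, 1))
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    rec <- static_recording(gdir = gdir, dur = 5, noise_acc = 0.1)
    q <- estimate_initial_orientation(rec)
    acos(pmin(1, sum(quat_rotate(q, gdir) * c(0, 0, 1)))) * 180 / pi
  }, numeric(1))
  expect_lt(max(errs), 0.5)
})

test_that("non-static initial window warns and proceeds", {
  rec <- static_recording(gdir = c(0, 1, 0), dur = 5, noise_gyr = 0.5)
  expect_warning(estimate_initial_orientation(rec), "not static")
})

test_that("fusion is constant under zero gyro and consistent gravity", {
  q0 <- quat_from_axis_angle(c(1, 0, 0), 0.3)
  gdir <- quat_rotate(quat_conjugate(q0), c(0, 0, 1))
  rec <- static_recording(gdir = gdir, dur = 2)
  tr <- fuse_orientation(rec, q0 = q0, gain = 0.1)
  expect_lt(max(quat_angle(cbind(tr$q1, tr$q2, tr$q3, tr$q4), q0)) * 180 / pi,
            0.01)
})

test_that("gravity correction cannot observe yaw but keeps tilt", {
  # constant 90 deg/s yaw for 1 s with accel = gravity: yaw integrates to
  # 90 degrees, roll/pitch stay below 1 degree
  fs <- 500
  t <- seq(0, 1, by = 1 / fs)
  n <- length(t)
  rec <- imu_recording(t, matrix(rep(c(0, 0, 9.81), each = n), n, 3),
                       matrix(rep(c(0, 0, pi / 2), each = n), n, 3),
                       fs = fs, frame = "anatomical")
  tr <- fuse_orientation(rec, q0 = c(1, 0, 0, 0), gain = 0.1)
  e <- quaternion_to_euler(c(tr$q1[n], tr$q2[n], tr$q3[n], tr$q4[n]))
  expect_equal(abs(e$psi) * 180 / pi, 90, tolerance = 1)
  expect_lt(max(abs(c(e$theta, e$phi))) * 180 / pi, 1)
})

test_that("fusion converges on a gravity-consistent tumble", {
  tb <- tumble_recording(rate = 30 * pi / 180, axis = c(1, 0, 0), dur = 4)
  q0_off <- quat_multiply(quat_from_axis_angle(c(0, 1, 0), 15 * pi / 180),
                          tb$q_true[1, ])
  tr <- fuse_orientation(tb$rec, q0 = q0_off, gain = 0.1)
  err <- quat_angle(cbind(tr$q1, tr$q2, tr$q3, tr$q4), tb$q_true) * 180 / pi
  expect_lt(err[2 * 500], 2)
  expect_lt(max(err[(2 * 500):length(err)]), 2)
})

test_that("fusion rejects empty or NA input", {
  rec <- static_recording(dur = 0.1)
  rec$acc_x[3] <- NA
  expect_error(fuse_orientation(rec), "NA")
  expect_error(fuse_orientation(rec[0, ]), "empty|positive")
})

test_that("rotate_to_global subtracts gravity and preserves vector norms", {
  rec <- static_recording(gdir = c(0, 0, 1), dur = 1)
  tr <- orientation_trace(rec$t, matrix(rep(c(1, 0, 0, 0), each = nrow(rec)),
                                        ncol = 4))
  out <- rotate_to_global(rec, tr)
  expect_identical(imu_frame(out), "global")
  expect_equal(max(abs(cbind(out$acc_x, out$acc_y, out$acc_z))), 0,
               tolerance = 1e-12)

  # random orientations: gyro rotation is an isometry
  set.seed(3)
  n <- 50
  q <- random_unit_quaternions(n)
  rec2 <- imu_recording(seq(0, (n - 1) / 500, by = 1 / 500),
                        matrix(rnorm(3 * n), n, 3), matrix(rnorm(3 * n), n, 3),
                        fs = 500, frame = "anatomical")
  out2 <- rotate_to_global(rec2, orientation_trace(rec2$t, q))
  expect_lt(max(abs(sqrt(out2$gyr_x^2 + out2$gyr_y^2 + out2$gyr_z^2) -
                      sqrt(rec2$gyr_x^2 + rec2$gyr_y^2 + rec2$gyr_z^2))), 1e-10)
})

test_that("a static recording ends up with near-zero motion acceleration", {
  set.seed(9)
  q0 <- quat_from_axis_angle(c(1, 0.2, 0), 0.4)
  gdir <- quat_rotate(quat_conjugate(q0), c(0, 0, 1))
  rec <- static_recording(gdir = gdir, dur = 5, noise_acc = 0.05,
                          noise_gyr = 0.01)
  tr <- fuse_orientation(rec, q0 = estimate_initial_orientation(rec))
  out <- rotate_to_global(rec, tr)
  expect_lt(max(abs(colMeans(cbind(out$acc_x, out$acc_y, out$acc_z)))), 0.05)
})
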