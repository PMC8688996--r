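# Shared fixtures: small constructed recordings and tumble simulations.

# anatomical-frame static recording with gravity along `gdir`
static_recording <- function(gdir = c(0, 0, 1), dur = 5, fs = 500,
                             noise_acc = 0, noise_gyr = 0,
                             frame = "anatomical") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  n <- length(t)
  gdir <- gdir / sqrt(sum(gdir^2))
  acc <- matrix(rep(9.81 * gdir, each = n), n, 3) +
    matrix(stats::rnorm(3 * n, 0, noise_acc), n, 3)
  gyr <- matrix(stats::rnorm(3 * n, 0, noise_gyr), n, 3)
  imu_recording(t, acc, gyr, fs = fs, frame = frame)
}

# noise-free (or noisy) rotation with gravity-consistent accelerometer:
# body rotates at `rate` rad/s about `axis` starting from identity
tumble_recording <- function(rate = 0.5, axis = c(1, 0, 0), dur = 4, fs = 500,
                             noise_acc = 0, noise_gyr = 0) {
  t <- seq(0, dur, by = 1 / fs)
  n <- length(t)
  q <- t(vapply(rate * t, function(a) quat_from_axis_angle(axis, a),
                numeric(4)))
  acc <- quat_rotate(quat_conjugate(q),
                     matrix(rep(c(0, 0, 9.81), each = n), n, 3)) +
    matrix(stats::rnorm(3 * n, 0, noise_acc), n, 3)
  axis <- axis / sqrt(sum(axis^2))
  gyr <- matrix(rep(rate * axis, each = n), n, 3) +
    matrix(stats::rnorm(3 * n, 0, noise_gyr), n, 3)
  list(rec = imu_recording(t, acc, gyr, fs = fs, frame = "anatomical"),
       q_true = q)
}

# global-frame recording built from explicit channel vectors (with Euler
# columns), for feature tests
global_recording <- function(t, acc_x = 0, acc_y = 0, acc_z = 0,
                             gyr_x = 0, gyr_y = 0, gyr_z = 0,
                             theta = 0, phi = 0, fs = 500) {
  n <- length(t)
  rec <- imu_recording(t,
                       cbind(rep_len(acc_x, n), rep_len(acc_y, n), rep_len(acc_z, n)),
                       cbind(rep_len(gyr_x, n), rep_len(gyr_y, n), rep_len(gyr_z, n)),
                       fs = fs, frame = "global")
  rec$psi <- rep_len(0, n)
  rec$theta <- rep_len(theta, n)
  rec$phi <- rep_len(phi, n)
  rec
}

random_unit_quaternions <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}
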