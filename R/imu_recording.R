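# IMU recording container and file formats.

#' Create an IMU recording
#'
#' An IMU recording is a tibble with columns `t` (s), `acc_x`, `acc_y`,
#' `acc_z` (m/s^2) and `gyr_x`, `gyr_y`, `gyr_z` (rad/s), uniformly sampled at
#' `fs` Hz, tagged with the frame its axes live in:
#'
#' * `sensor` - raw device axes;
#' * `anatomical` - body-fixed axes after functional calibration
#'   (x = mediolateral, y = longitudinal, cranial positive,
#'   z = anterior-posterior);
#' * `global` - pool-fixed axes (X = lateral, Y = swimming direction,
#'   Z = vertical up). Global recordings may additionally carry the Euler
#'   angle columns `psi`, `theta`, `phi`.
#'
#' @param t Time vector, seconds, strictly increasing at a fixed step.
#' @param acc n x 3 matrix or data frame of accelerations (m/s^2).
#' @param gyr n x 3 matrix or data frame of angular velocities (rad/s).
#' @param fs Sampling rate in Hz.
#' @param frame One of `"sensor"`, `"anatomical"`, `"global"`.
#' @return A tibble of class `imu_recording` with attributes `fs` and `frame`.
#' @export
imu_recording <- function(t, acc, gyr, fs, frame = c("sensor", "anatomical", "global")) {
  frame <- match.arg(frame)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  stopifnot(ncol(acc) == 3L, ncol(gyr) == 3L)
  if (length(t) != nrow(acc) || length(t) != nrow(gyr)) {
    stop("t, acc and gyr must have the same number of samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(t) > 1L && max(abs(diff(t) - 1 / fs)) > 1e-6) {
    stop("t must advance in uniform steps of 1/fs")
  }
  out <- tibble::tibble(
    t = as.numeric(t),
    acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
    gyr_x = gyr[, 1], gyr_y = gyr[, 2], gyr_z = gyr[, 3]
  )
  new_imu_recording(out, fs = fs, frame = frame)
}

new_imu_recording <- function(df, fs, frame) {
  structure(df, fs = fs, frame = frame,
            class = c("imu_recording", class(tibble::tibble())))
}

#' @rdname imu_recording
#' @param rec An `imu_recording`.
#' @export
imu_fs <- function(rec) attr(rec, "fs")

#' @rdname imu_recording
#' @export
imu_frame <- function(rec) attr(rec, "frame")

assert_frame <- function(rec, frame) {
  if (!identical(imu_frame(rec), frame)) {
    stop(sprintf("recording must be in the '%s' frame, got '%s'",
                 frame, imu_frame(rec)), call. = FALSE)
  }
  invisible(rec)
}

imu_acc <- function(rec) cbind(rec$acc_x, rec$acc_y, rec$acc_z)
imu_gyr <- function(rec) cbind(rec$gyr_x, rec$gyr_y, rec$gyr_z)

#' Read and write IMU CSV files
#'
#' The on-disk format is a CSV with header `t,acc_x,acc_y,acc_z,gyr_x,gyr_y,
#' gyr_z` (SI units) plus a sidecar YAML file (`<path>.yaml`) recording `fs`,
#' `frame` and the units.
#'
#' @param path CSV path; the sidecar is `paste0(path, ".yaml")`.
#' @param rec An `imu_recording` (for writing).
#' @return `read_imu_csv()` returns an `imu_recording`; `write_imu_csv()`
#'   returns `path` invisibly.
#' @export
read_imu_csv <- function(path) {
  meta_path <- paste0(path, ".yaml")
  if (!file.exists(meta_path)) stop("missing sidecar metadata file: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  imu_recording(df$t,
                cbind(df$acc_x, df$acc_y, df$acc_z),
                cbind(df$gyr_x, df$gyr_y, df$gyr_z),
                fs = meta$fs, frame = meta$frame)
}

#' @rdname read_imu_csv
#' @export
write_imu_csv <- function(rec, path) {
  readr::write_csv(tibble::as_tibble(rec)[c("t", "acc_x", "acc_y", "acc_z",
                                            "gyr_x", "gyr_y", "gyr_z")], path,
                   progress = FALSE)
  yaml::write_yaml(
    list(fs = imu_fs(rec), frame = imu_frame(rec),
         units = list(t = "s", acc = "m/s^2", gyr = "rad/s")),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' Intrinsic and anatomical calibration parameters
#'
#' Holds, per sensor, the offset (bias), the combined scale/non-orthogonality
#' matrix and the sensor-to-anatomical alignment rotation applied by
#' [apply_calibration()].
#'
#' @param acc_bias,gyr_bias Length-3 offsets (m/s^2, rad/s).
#' @param acc_scale,gyr_scale 3 x 3 invertible scale/non-orthogonality
#'   matrices.
#' @param r_sensor_to_anatomical 3 x 3 rotation mapping sensor axes to
#'   anatomical axes (orthonormal, det +1).
#' @return A list of class `calibration_params`.
#' @export
calibration_params <- function(acc_bias = c(0, 0, 0), gyr_bias = c(0, 0, 0),
                               acc_scale = diag(3), gyr_scale = diag(3),
                               r_sensor_to_anatomical = diag(3)) {
  acc_scale <- as.matrix(acc_scale); gyr_scale <- as.matrix(gyr_scale)
  r <- as.matrix(r_sensor_to_anatomical)
  stopifnot(length(acc_bias) == 3L, length(gyr_bias) == 3L,
            all(dim(acc_scale) == 3L), all(dim(gyr_scale) == 3L),
            all(dim(r) == 3L))
  for (m in list(acc_scale, gyr_scale)) {
    if (abs(det(m)) < 1e-12) stop("scale/non-orthogonality matrix is not invertible")
  }
  if (max(abs(crossprod(r) - diag(3))) > 1e-6 || det(r) < 0.99) {
    stop("r_sensor_to_anatomical must be a proper rotation (orthonormal, det +1)")
  }
  structure(list(acc_bias = as.numeric(acc_bias), gyr_bias = as.numeric(gyr_bias),
                 acc_scale = acc_scale, gyr_scale = gyr_scale,
                 r_sensor_to_anatomical = r),
            class = "calibration_params")
}

#' Read and write calibration YAML files
#'
#' Bias vectors are stored as length-3 sequences and matrices row-major.
#'
#' @param path YAML file path.
#' @param cal A `calibration_params` object (for writing).
#' @export
read_calibration_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  as_mat <- function(x) matrix(unlist(x), nrow = 3, byrow = TRUE)
  calibration_params(
    acc_bias = unlist(y$acc_bias), gyr_bias = unlist(y$gyr_bias),
    acc_scale = as_mat(y$acc_scale), gyr_scale = as_mat(y$gyr_scale),
    r_sensor_to_anatomical = as_mat(y$r_sensor_to_anatomical)
  )
}

#' @rdname read_calibration_yaml
#' @export
write_calibration_yaml <- function(cal, path) {
  row_major <- function(m) lapply(seq_len(3), function(i) as.numeric(m[i, ]))
  yaml::write_yaml(list(
    acc_bias = as.numeric(cal$acc_bias), gyr_bias = as.numeric(cal$gyr_bias),
    acc_scale = row_major(cal$acc_scale), gyr_scale = row_major(cal$gyr_scale),
    r_sensor_to_anatomical = row_major(cal$r_sensor_to_anatomical)
  ), path)
  invisible(path)
}
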