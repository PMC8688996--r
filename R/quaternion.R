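# Quaternion algebra for orientation handling.
#
# Quaternions are stored as numeric vectors of length 4 or as n x 4 matrices
# (one row per sample), with components (q1, q2, q3, q4) where q1 is the
# scalar part. All rotation quaternions are unit-norm Hamilton quaternions
# and rotate body-frame (anatomical) vectors into the global frame:
#   v_global = q (x) [0, v_body] (x) q*

#' Quaternion multiplication
#'
#' Hamilton product of two quaternions (or two row-wise matched sets of
#' quaternions given as n x 4 matrices). The first component is the scalar
#' part.
#'
#' @param p,q Numeric vectors of length 4, or n x 4 matrices.
#' @return A vector of length 4, or an n x 4 matrix.
#' @export
quat_multiply <- function(p, q) {
  p <- quat_as_matrix(p)
  q <- quat_as_matrix(q)
  if (nrow(p) == 1L && nrow(q) > 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1L && nrow(p) > 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
  stopifnot(nrow(p) == nrow(q))
  out <- cbind(
    p[, 1] * q[, 1] - p[, 2] * q[, 2] - p[, 3] * q[, 3] - p[, 4] * q[, 4],
    p[, 1] * q[, 2] + p[, 2] * q[, 1] + p[, 3] * q[, 4] - p[, 4] * q[, 3],
    p[, 1] * q[, 3] - p[, 2] * q[, 4] + p[, 3] * q[, 1] + p[, 4] * q[, 2],
    p[, 1] * q[, 4] + p[, 2] * q[, 3] - p[, 3] * q[, 2] + p[, 4] * q[, 1]
  )
  quat_drop(out)
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(q) {
  q <- quat_as_matrix(q)
  quat_drop(cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4]))
}

#' @rdname quat_multiply
#' @export
quat_normalize <- function(q) {
  q <- quat_as_matrix(q)
  n <- sqrt(rowSums(q^2))
  if (any(n < 1e-12)) stop("cannot normalize a zero quaternion")
  quat_drop(q / n)
}

quat_as_matrix <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop("quaternion matrices must have 4 columns")
    q
  } else {
    if (length(q) != 4L) stop("a quaternion has 4 components")
    matrix(q, nrow = 1L)
  }
}

quat_drop <- function(q) if (nrow(q) == 1L) drop(q) else q

#' Rotate 3-vectors by quaternions
#'
#' Applies `v_out = q (x) [0, v] (x) q*`, i.e. rotates body-frame vectors into
#' the global frame. Vectorized over rows.
#'
#' @param q Unit quaternion(s): length-4 vector or n x 4 matrix.
#' @param v 3-vector or n x 3 matrix of vectors to rotate.
#' @return Rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  q <- quat_as_matrix(q)
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(vm) != 3L) stop("vectors must have 3 components")
  if (nrow(q) == 1L && nrow(vm) > 1L) q <- q[rep(1L, nrow(vm)), , drop = FALSE]
  if (nrow(vm) == 1L && nrow(q) > 1L) vm <- vm[rep(1L, nrow(q)), , drop = FALSE]
  p <- quat_multiply(
    quat_multiply(q, cbind(0, vm)),
    quat_conjugate(q)
  )
  p <- quat_as_matrix(p)
  out <- p[, 2:4, drop = FALSE]
  if (!is.matrix(v)) drop(out) else out
}

#' Build a quaternion from an axis and angle
#'
#' @param axis Rotation axis, length-3 (need not be normalized).
#' @param angle Rotation angle in radians (right-hand rule about `axis`).
#' @return A unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Rotation matrix of a unit quaternion
#'
#' Returns the 3 x 3 matrix R with `R v_body = v_global`, equal to the
#' quaternion sandwich product. Used as an independent oracle for
#' [quat_rotate()].
#'
#' @param q Unit quaternion, length 4.
#' @return A 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4L)
  q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]
  matrix(c(
    1 - 2 * (q3^2 + q4^2), 2 * (q2 * q3 - q1 * q4), 2 * (q2 * q4 + q1 * q3),
    2 * (q2 * q3 + q1 * q4), 1 - 2 * (q2^2 + q4^2), 2 * (q3 * q4 - q1 * q2),
    2 * (q2 * q4 - q1 * q3), 2 * (q3 * q4 + q1 * q2), 1 - 2 * (q2^2 + q3^2)
  ), nrow = 3, byrow = TRUE)
}

#' Geodesic angle between two quaternions
#'
#' Smallest rotation angle (radians) taking one orientation to the other;
#' insensitive to the q / -q double cover.
#'
#' @param p,q Unit quaternions (length 4 or n x 4).
#' @return Angle(s) in radians, in `[0, pi]`.
#' @export
quat_angle <- function(p, q) {
  p <- quat_as_matrix(p)
  q <- quat_as_matrix(q)
  if (nrow(p) == 1L && nrow(q) > 1L) p <- p[rep(1L, nrow(q)), , drop = FALSE]
  if (nrow(q) == 1L && nrow(p) > 1L) q <- q[rep(1L, nrow(p)), , drop = FALSE]
  d <- pmin(1, abs(rowSums(p * q)))
  ang <- 2 * acos(d)
  if (length(ang) == 1L) drop(ang) else ang
}

#' Spherical linear interpolation between two quaternions
#'
#' @param q0,q1 Unit quaternions (length 4).
#' @param s Interpolation fraction(s) in `[0, 1]`; vectorized.
#' @return A unit quaternion, or an n x 4 matrix when `s` has length > 1.
#' @export
quat_slerp <- function(q0, q1, s) {
  stopifnot(length(q0) == 4L, length(q1) == 4L)
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  d <- min(1, d)
  om <- acos(d)
  if (om < 1e-9) {
    out <- outer(1 - s, q0) + outer(s, q1)
  } else {
    out <- outer(sin((1 - s) * om) / sin(om), q0) +
      outer(sin(s * om) / sin(om), q1)
  }
  quat_drop(quat_as_matrix(quat_normalize(out)))
}

#' Convert quaternions to Euler angles
#'
#' Yaw (psi), roll (theta) and pitch (phi) of the sacrum, defined about the
#' anterior-posterior, longitudinal and mediolateral anatomical axes
#' respectively:
#' \deqn{\psi = \mathrm{atan2}(2 q_2 q_3 - 2 q_1 q_4,\; 2 q_1^2 + 2 q_2^2 - 1)}
#' \deqn{\theta = -\sin^{-1}(2 q_2 q_4 + 2 q_1 q_3)}
#' \deqn{\phi = \mathrm{atan2}(2 q_3 q_4 - 2 q_1 q_2,\; 2 q_1^2 + 2 q_4^2 - 1)}
#'
#' These are the ZYX angles of the transpose of the body-to-global rotation,
#' so a body rotation of +a about the longitudinal (y) axis reads theta = -a;
#' the sign convention is fixed by requiring exact round-trip consistency with
#' [euler_to_quaternion()]. Near gimbal lock (|theta| -> 90 deg) the asin
#' argument is clamped to [-1, 1] with a warning.
#'
#' @param q Unit quaternion(s): length-4 vector or n x 4 matrix.
#' @return A tibble with columns `psi`, `theta`, `phi` (radians).
#' @export
quaternion_to_euler <- function(q) {
  q <- quat_as_matrix(q)
  q1 <- q[, 1]; q2 <- q[, 2]; q3 <- q[, 3]; q4 <- q[, 4]
  s <- 2 * q2 * q4 + 2 * q1 * q3
  if (any(abs(s) > 1)) {
    warning("gimbal-lock argument outside [-1, 1]; clamped")
    s <- pmin(1, pmax(-1, s))
  }
  tibble::tibble(
    psi = atan2(2 * q2 * q3 - 2 * q1 * q4, 2 * q1^2 + 2 * q2^2 - 1),
    theta = -asin(s),
    phi = atan2(2 * q3 * q4 - 2 * q1 * q2, 2 * q1^2 + 2 * q4^2 - 1)
  )
}

#' Convert Euler angles back to a quaternion
#'
#' Exact inverse of [quaternion_to_euler()] away from gimbal lock:
#' `q = conj(qz(psi) (x) qy(theta) (x) qx(phi))`.
#'
#' @param psi,theta,phi Angles in radians (vectorized).
#' @return A unit quaternion or n x 4 matrix.
#' @export
euler_to_quaternion <- function(psi, theta, phi) {
  n <- max(length(psi), length(theta), length(phi))
  psi <- rep_len(psi, n); theta <- rep_len(theta, n); phi <- rep_len(phi, n)
  qz <- cbind(cos(psi / 2), 0, 0, sin(psi / 2))
  qy <- cbind(cos(theta / 2), 0, sin(theta / 2), 0)
  qx <- cbind(cos(phi / 2), sin(phi / 2), 0, 0)
  q <- quat_conjugate(quat_multiply(quat_multiply(qz, qy), qx))
  quat_drop(quat_as_matrix(q))
}
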