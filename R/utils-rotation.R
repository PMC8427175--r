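# Rotation, quaternion and angle utilities.
#
# Conventions (fixed package-wide):
#  * quaternions are length-4 numeric c(w, x, y, z), unit norm, mapping body
#    frame -> inertial frame: v_world = quat_to_rot(q) %*% v_body
#  * Euler angles are Z-Y-X (yaw psi, pitch alpha, roll beta), right-handed,
#    body-fixed: R = Rz(psi) Ry(alpha) Rx(beta)
#  * all internal angles are radians; degrees appear only at user interfaces

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rotation matrix about an arbitrary unit axis
#'
#' Rodrigues' formula for a right-handed rotation by `angle` radians about
#' unit vector `axis`.
#'
#' @param axis unit 3-vector.
#' @param angle rotation angle, radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_axis_angle <- function(axis, angle) {
  K <- skew3(axis)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

quat_from_axis_angle <- function(axis, angle) {
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# quaternion derivative for body-frame angular velocity omega
quat_derivative <- function(q, omega) {
  0.5 * quat_multiply(q, c(0, omega))
}

# Z-Y-X Euler angles (yaw, pitch, roll) from a unit quaternion
quat_to_euler_zyx <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  sp <- 2 * (w * y - z * x)
  sp <- pmin(1, pmax(-1, sp))
  c(yaw   = atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2)),
    pitch = asin(sp),
    roll  = atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2)))
}

# Body angular velocity from Euler-angle rates: omega = E %*% c(psi., alpha., beta.)
euler_rate_matrix <- function(alpha, beta) {
  matrix(c(-sin(alpha), cos(alpha) * sin(beta), cos(alpha) * cos(beta),
           0, cos(beta), -sin(beta),
           1, 0, 0), 3, 3)
}

# Euler-angle rates (psi., alpha., beta.) from body angular velocity
euler_rates_from_omega <- function(alpha, beta, omega) {
  ca <- cos(alpha)
  if (abs(ca) < 1e-8) ca <- sign(ca + .Machine$double.eps) * 1e-8
  sb <- sin(beta); cb <- cos(beta)
  h <- sb * omega[2] + cb * omega[3]
  c(h / ca,
    cb * omega[2] - sb * omega[3],
    omega[1] + tan(alpha) * h)
}

#' Unwrap a phase angle sequence
#'
#' Removes jumps larger than half a revolution so consecutive samples differ
#' by less than `period / 2`.
#'
#' @param x numeric vector of angles.
#' @param period full revolution (default `2 * pi`; use 360 for degrees).
#' @return unwrapped vector, same first element as `x`.
#' @export
unwrap_angle <- function(x, period = 2 * pi) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  d <- d - period * round(d / period)
  cumsum(c(x[1], d))
}
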