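#' Rotation about a coordinate axis
#'
#' Right-handed rotation matrix about x, y or z by an angle in degrees.
#'
#' @param axis One of "x", "y", "z".
#' @param angle_deg Rotation angle in degrees (right-handed about the axis).
#' @return A 3x3 rotation matrix.
#' @export
rot_axis <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
    x = matrix(c(1, 0, 0, 0, c_, s_, 0, -s_, c_), 3, 3),
    y = matrix(c(c_, 0, -s_, 0, 1, 0, s_, 0, c_), 3, 3),
    z = matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
  )
}

#' Rotation about an arbitrary unit axis
#'
#' @param u Axis (length-3, normalised internally).
#' @param angle_deg Angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues form).
#' @export
rot_about <- function(u, angle_deg) {
  u <- u / sqrt(sum(u^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Euler angles (intrinsic Z-X-Z) to rotation matrix
#'
#' The convention used throughout: intrinsic Z-X-Z in degrees, i.e.
#' R = Rz(phi) Rx(theta) Rz(psi).
#'
#' @param euler Numeric length-3 (phi, theta, psi) in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(euler) {
  rot_axis("z", euler[1]) %*% rot_axis("x", euler[2]) %*% rot_axis("z", euler[3])
}

#' Rotation matrix to Euler angles (intrinsic Z-X-Z, degrees)
#'
#' @param R 3x3 rotation matrix.
#' @return Numeric length-3 (phi, theta, psi) in degrees.
#' @export
matrix_to_euler <- function(R) {
  theta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(theta)) < 1e-9) {
    # gimbal: fold everything into phi
    phi <- atan2(R[2, 1], R[1, 1])
    if (R[3, 3] < 0) phi <- atan2(-R[2, 1], R[1, 1])
    return(c(phi, theta, 0) * 180 / pi)
  }
  phi <- atan2(R[1, 3], -R[2, 3])
  psi <- atan2(R[3, 1], R[3, 2])
  c(phi, theta, psi) * 180 / pi
}

#' Signed angle from +x axis to a 2D vector, in degrees
#' @param v Length-2 numeric.
#' @return Angle in degrees in (-180, 180].
#' @export
angle2d <- function(v) atan2(v[2], v[1]) * 180 / pi

#' Wrap an angle into (-period/2, period/2]
#' @param a Angle in degrees.
#' @param period Wrapping period in degrees.
#' @return Wrapped angle.
#' @export
wrap_angle <- function(a, period = 360) {
  w <- a - period * round(a / period)
  ifelse(w <= -period / 2, w + period, w)
}
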