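#' Quaternion utilities
#'
#' Orientation is represented as a Hamilton unit quaternion in scalar-first
#' order `(w, x, y, z)`, encoding the rotation that takes device-frame
#' vectors into the world frame.
#'
#' @name quaternion
NULL

#' Normalize a quaternion to unit length
#'
#' Quaternions within `tol` of unit norm are renormalized; anything further
#' away is treated as corrupt and rejected.
#'
#' @param q numeric length-4 vector `(w, x, y, z)`.
#' @param tol maximum allowed deviation of `|q|` from 1 before the input is
#'   considered invalid (default `1e-3`, generous enough for fixed-point
#'   quantization of on-board sensor fusion output).
#' @return unit-norm quaternion.
#' @export
quat_normalize <- function(q, tol = 1e-3) {
  stopifnot(is.numeric(q), length(q) == 4L)
  nrm <- sqrt(sum(q^2))
  if (!is.finite(nrm) || nrm < .Machine$double.eps^0.5) {
    stop("near-zero or non-finite quaternion cannot be normalized")
  }
  if (abs(nrm - 1) > tol) {
    stop(sprintf("quaternion norm %.6f deviates from 1 by more than %g", nrm, tol))
  }
  q / nrm
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#'
#' @inheritParams quat_normalize
#' @return 3x3 proper rotation matrix `R` with `R %*% v_device = v_world`.
#' @examples
#' quat_to_rotation(c(1, 0, 0, 0))            # identity
#' quat_to_rotation(c(sqrt(0.5), 0, 0, sqrt(0.5)))  # 90 deg about z
#' @export
quat_to_rotation <- function(q, tol = 1e-3) {
  q <- quat_normalize(q, tol = tol)
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' Quaternion conjugate (inverse rotation for unit quaternions)
#' @inheritParams quat_normalize
#' @return conjugate quaternion `(w, -x, -y, -z)`.
#' @export
quat_conjugate <- function(q) {
  stopifnot(length(q) == 4L)
  c(q[1L], -q[2L], -q[3L], -q[4L])
}

#' Draw a uniformly distributed random unit quaternion
#'
#' Uses the standard subgroup-algorithm construction from three uniforms,
#' giving the Haar-uniform distribution on SO(3).
#'
#' @return unit quaternion `(w, x, y, z)`.
#' @export
random_quaternion <- function() {
  u <- stats::runif(3L)
  c(
    sqrt(1 - u[1L]) * sin(2 * pi * u[2L]),
    sqrt(1 - u[1L]) * cos(2 * pi * u[2L]),
    sqrt(u[1L]) * sin(2 * pi * u[3L]),
    sqrt(u[1L]) * cos(2 * pi * u[3L])
  )
}

#' Rotate row vectors by a quaternion
#'
#' @param v n x 3 matrix of vectors.
#' @param q unit quaternion (device-to-world).
#' @param inverse if `TRUE`, apply the inverse (world-to-device) rotation.
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(v, q, inverse = FALSE) {
  v <- rbind(v)
  stopifnot(ncol(v) == 3L)
  R <- quat_to_rotation(q)
  if (inverse) R <- t(R)
  v %*% t(R)
}
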