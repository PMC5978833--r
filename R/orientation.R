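# Quaternion and rotation-matrix kinematics: IMU orientation samples to
# reference-relative spherical arm coordinates (azimuth alpha, elevation beta).
#
# Frame convention (right-handed): +z points along the hanging arm in the
# neutral pose, so elevation beta = 0 at rest; +x is anterior (flexion plane
# at alpha = 0); +y points to the subject's lateral side, so alpha = +90 deg
# is the abduction plane and |alpha| -> 180 deg is posterior.

#' Wrap angles in degrees into (-180, 180]
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap180 <- function(a) {
  w <- a %% 360
  ifelse(w > 180, w - 360, w)
}

# Validate and renormalize a unit quaternion c(qw, qx, qy, qz).
# Deviations of the norm from 1 up to `tol` are silently repaired;
# larger deviations raise an invalid-sample error naming the timestamp.
check_unit_quaternion <- function(q, tol = 1e-3, t = NA_real_) {
  q <- as.numeric(q)
  if (length(q) != 4L || anyNA(q)) {
    stop("quaternion must be four finite numbers (qw, qx, qy, qz)")
  }
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > tol) {
    where <- if (is.finite(t)) sprintf(" at t = %g s", t) else ""
    stop(sprintf(
      "invalid quaternion sample%s: |q| = %.6f deviates from 1 by more than %g",
      where, n, tol
    ))
  }
  q / n
}

#' Canonicalize the sign of a unit quaternion
#'
#' `q` and `-q` encode the same rotation; the canonical representative has
#' `qw >= 0`, which makes round trips through the simulator deterministic.
#'
#' @param q numeric vector `c(qw, qx, qy, qz)`.
#' @return the canonical quaternion.
#' @export
canonical_quaternion <- function(q) {
  if (q[1] < 0) -q else q
}

#' Convert a unit quaternion to its rotation matrix
#'
#' Maps an orientation quaternion \eqn{q = qw + i\,qx + j\,qy + k\,qz} to the
#' unique 3x3 rotation matrix that applies the same (active) rotation to
#' column vectors.
#'
#' @param q numeric vector `c(qw, qx, qy, qz)`, unit norm within `tol`.
#' @param tol maximum tolerated deviation of the quaternion norm from 1;
#'   smaller deviations are repaired by renormalization.
#' @param t optional timestamp (seconds) used in error messages.
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @examples
#' quat_to_rotmat(c(1, 0, 0, 0))           # identity
#' quat_to_rotmat(c(sqrt(2)/2, sqrt(2)/2, 0, 0))  # +90 deg about x
#' @export
quat_to_rotmat <- function(q, tol = 1e-3, t = NA_real_) {
  q <- check_unit_quaternion(q, tol = tol, t = t)
  qw <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  matrix(c(
    qw^2 + qx^2 - qy^2 - qz^2, 2 * qx * qy - 2 * qw * qz, 2 * qx * qz + 2 * qw * qy,
    2 * qx * qy + 2 * qw * qz, qw^2 - qx^2 + qy^2 - qz^2, 2 * qy * qz - 2 * qw * qx,
    2 * qx * qz - 2 * qw * qy, 2 * qy * qz + 2 * qw * qx, qw^2 - qx^2 - qy^2 + qz^2
  ), nrow = 3, byrow = TRUE)
}

#' Test whether a matrix is a proper rotation
#'
#' @param R a 3x3 matrix.
#' @param tol tolerance on orthonormality and on `det(R) = 1`.
#' @return `TRUE` if `R` is orthonormal with determinant +1 within `tol`.
#' @export
is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

assert_rotation <- function(R, tol = 1e-6, name = "R") {
  if (!is_rotation(R, tol = tol)) {
    stop(sprintf("invalid rotation matrix '%s': not orthonormal with det +1 within %g",
                 name, tol))
  }
  invisible(R)
}

#' Orientation relative to a reference pose
#'
#' Expresses an arm orientation `R` relative to the neutral-pose reference
#' `R0` as `R0^-1 %*% R`; the inverse of a rotation is its transpose, which
#' is exact and numerically stable.
#'
#' @param R,R0 3x3 rotation matrices (current and reference orientation).
#' @return the relative rotation matrix.
#' @export
relative_rotation <- function(R, R0) {
  assert_rotation(R, name = "R")
  assert_rotation(R0, name = "R0")
  t(R0) %*% R
}

#' Rotate a Cartesian point
#'
#' @param R a 3x3 rotation matrix.
#' @param p0 numeric vector `c(x, y, z)` with positive norm.
#' @return the rotated point `R %*% p0` as a numeric vector; norms are
#'   preserved.
#' @export
rotate_point <- function(R, p0) {
  assert_rotation(R)
  p0 <- as.numeric(p0)
  if (length(p0) != 3L || !all(is.finite(p0))) stop("point must be three finite numbers")
  if (sum(p0^2) == 0) stop("degenerate direction: point has zero norm")
  as.numeric(R %*% p0)
}

#' Cartesian to spherical arm coordinates
#'
#' Converts arm-direction coordinates to spherical pose angles in degrees:
#' radius \eqn{r = \sqrt{x^2+y^2+z^2}}, elevation \eqn{\beta = \arccos(z/r)}
#' (0 at the neutral hanging arm, 180 fully inverted), and azimuth
#' \eqn{\alpha = \mathrm{atan2}(y, x)} using the full-quadrant two-argument
#' arctangent so that posterior azimuths are representable.
#'
#' @param p numeric vector `c(x, y, z)` or an n-by-3 matrix / data frame of
#'   such rows.
#' @return a data frame with columns `alpha` (degrees, in (-180, 180]),
#'   `beta` (degrees, in [0, 180]) and `r` (input length units).
#' @examples
#' to_spherical(c(0, 0, 1))  # neutral: beta = 0
#' to_spherical(c(1, 0, 0))  # anterior horizontal: beta = 90, alpha = 0
#' @export
to_spherical <- function(p) {
  m <- if (is.matrix(p) || is.data.frame(p)) as.matrix(p) else matrix(as.numeric(p), nrow = 1)
  if (ncol(m) != 3L) stop("expected 3 Cartesian coordinates per point")
  storage.mode(m) <- "double"
  r <- sqrt(rowSums(m^2))
  if (any(!is.finite(r)) || any(r == 0)) {
    stop("degenerate direction: zero-norm or non-finite point")
  }
  beta <- acos(pmin(pmax(m[, 3] / r, -1), 1)) * 180 / pi
  alpha <- atan2(m[, 2], m[, 1]) * 180 / pi
  data.frame(alpha = alpha, beta = beta, r = r)
}

#' Spherical arm coordinates to Cartesian
#'
#' Inverse of [to_spherical()] on the angles.
#'
#' @param alpha azimuth, degrees.
#' @param beta elevation, degrees.
#' @param r radius (default 1: only the direction carries ROM information).
#' @return an n-by-3 matrix of Cartesian coordinates.
#' @export
spherical_to_cartesian <- function(alpha, beta, r = 1) {
  a <- alpha * pi / 180
  b <- beta * pi / 180
  cbind(x = r * sin(b) * cos(a), y = r * sin(b) * sin(a), z = r * cos(b))
}

#' Convert a quaternion stream to spherical arm poses
#'
#' Runs the full orientation chain per sample: quaternion -> rotation matrix,
#' rotation relative to the neutral-pose reference, rotation of the arm
#' direction vector, and conversion to spherical coordinates. Tracking a
#' single body-fixed direction discards axial rotation of the humerus about
#' its long axis, which is what keeps the output free of Codman's paradox.
#'
#' @param stream data frame with columns `t, qw, qx, qy, qz` (plus any extra
#'   columns, which are ignored); timestamps strictly increasing.
#' @param reference the neutral-pose orientation: `NULL` to use the first
#'   sample, or a quaternion `c(qw, qx, qy, qz)`.
#' @param arm_direction body-fixed arm direction in the sensor frame at
#'   neutral; default `c(0, 0, 1)` (unit vector along the hanging arm).
#' @param tol quaternion-norm tolerance passed to validation.
#' @return a data frame with columns `t`, `alpha`, `beta`, `r`.
#' @export
stream_to_poses <- function(stream, reference = NULL, arm_direction = c(0, 0, 1),
                            tol = 1e-3) {
  need <- c("t", "qw", "qx", "qy", "qz")
  if (!is.data.frame(stream) || !all(need %in% names(stream))) {
    stop("stream must be a data frame with columns t, qw, qx, qy, qz")
  }
  if (nrow(stream) == 0L) stop("empty quaternion stream")
  if (any(diff(stream$t) <= 0)) stop("non-monotone timestamps in quaternion stream")
  arm_direction <- as.numeric(arm_direction)
  if (length(arm_direction) != 3L || sum(arm_direction^2) == 0) {
    stop("degenerate direction: arm_direction must be a nonzero 3-vector")
  }

  Q <- as.matrix(stream[, c("qw", "qx", "qy", "qz")])
  storage.mode(Q) <- "double"
  nrm <- sqrt(rowSums(Q^2))
  bad <- which(abs(nrm - 1) > tol)
  if (length(bad)) {
    stop(sprintf(
      "invalid quaternion sample at t = %g s: |q| = %.6f deviates from 1 by more than %g",
      stream$t[bad[1]], nrm[bad[1]], tol
    ))
  }
  Q <- Q / nrm
  flip <- Q[, 1] < 0
  Q[flip, ] <- -Q[flip, ]

  if (is.null(reference)) {
    qref <- Q[1, ]
  } else {
    qref <- canonical_quaternion(check_unit_quaternion(reference, tol = tol))
  }
  R0 <- quat_to_rotmat(qref)

  # Vectorized sandwich product v = q * (0, a) * q^-1, i.e. R_i %*% a,
  # then the reference-relative pose R0^T (R_i a) — identical to composing
  # relative_rotation() and rotate_point() per sample.
  a <- arm_direction
  qv <- Q[, 2:4, drop = FALSE]
  tt <- 2 * cbind(qv[, 2] * a[3] - qv[, 3] * a[2],
                  qv[, 3] * a[1] - qv[, 1] * a[3],
                  qv[, 1] * a[2] - qv[, 2] * a[1])
  v <- matrix(a, nrow = nrow(Q), ncol = 3, byrow = TRUE) + Q[, 1] * tt +
    cbind(qv[, 2] * tt[, 3] - qv[, 3] * tt[, 2],
          qv[, 3] * tt[, 1] - qv[, 1] * tt[, 3],
          qv[, 1] * tt[, 2] - qv[, 2] * tt[, 1])
  u <- v %*% R0  # (R0^T v^T)^T = v R0

  sph <- to_spherical(u)
  data.frame(t = stream$t, sph)
}
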