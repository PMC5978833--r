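# Independent oracles used across the suite. These deliberately avoid the
# package's own rotation-matrix path.

# Hamilton product of two quaternions c(w, x, y, z)
qmul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

qconj <- function(q) c(q[1], -q[2:4])

# Rotate vector v by unit quaternion q via the sandwich product q (0,v) q*
sandwich_rotate <- function(q, v) {
  qmul(qmul(q, c(0, v)), qconj(q))[2:4]
}

# Rotation matrix from axis-angle (degrees), via Rodrigues' formula
axis_rotmat <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# n random unit quaternions (rows), canonical qw >= 0
random_unit_quats <- function(n) {
  m <- matrix(stats::rnorm(4 * n), ncol = 4)
  m <- m / sqrt(rowSums(m^2))
  m[m[, 1] < 0, ] <- -m[m[, 1] < 0, ]
  m
}

# Quaternion stream data frame from commanded spherical angles
angles_to_stream <- function(alpha, beta, rate = 100) {
  q <- spherical_to_quaternion(alpha, beta)
  data.frame(t = seq_along(alpha) / rate, q)
}

# Monte-Carlo solid-angle area (deg^2) of an envelope profile:
# fraction of uniformly distributed sphere points lying under the envelope.
mc_solid_angle_area <- function(env, n = 1e6) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, -pi, pi)
  alpha <- phi * 180 / pi
  beta <- acos(z) * 180 / pi
  idx <- pmax(ceiling((alpha + 180) / env$bin_width), 1L)
  bmax <- env$beta_max[idx]
  under <- !is.na(bmax) & beta <= bmax
  mean(under) * 4 * pi * (180 / pi)^2
}
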