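# Quaternion -> rotation matrix -> reference-relative spherical pose chain.

test_that("quaternion-to-matrix conversion matches the sandwich-product oracle", {
  expect_equal(quat_to_rotmat(c(1, 0, 0, 0)), diag(3))

  # +90 deg about x carries (0,0,1) to (0,-1,0)
  R <- quat_to_rotmat(c(sqrt(2) / 2, sqrt(2) / 2, 0, 0))
  expect_equal(as.numeric(R %*% c(0, 0, 1)), c(0, -1, 0), tolerance = 1e-12)
  expect_equal(as.numeric(R %*% c(0, 0, 1)),
               sandwich_rotate(c(sqrt(2) / 2, sqrt(2) / 2, 0, 0), c(0, 0, 1)),
               tolerance = 1e-12)

  set.seed(42)
  Q <- random_unit_quats(500)
  for (i in seq_len(nrow(Q))) {
    q <- Q[i, ]
    R <- quat_to_rotmat(q)
    expect_true(is_rotation(R, tol = 1e-9))
    v <- stats::rnorm(3)
    expect_lt(max(abs(as.numeric(R %*% v) - sandwich_rotate(q, v))), 1e-9)
  }
})

test_that("quaternion norm is repaired within tolerance, rejected beyond it", {
  q <- c(1 + 5e-4, 0, 0, 0)
  expect_equal(quat_to_rotmat(q), diag(3), tolerance = 1e-9)
  expect_error(quat_to_rotmat(c(1.1, 0, 0, 0), t = 3.25),
               "invalid quaternion sample at t = 3.25")
})

test_that("relative rotation composes and inverts correctly", {
  Rz30 <- axis_rotmat(c(0, 0, 1), 30)
  Rz50 <- axis_rotmat(c(0, 0, 1), 50)
  expect_equal(relative_rotation(Rz30, Rz30), diag(3), tolerance = 1e-12)
  expect_equal(relative_rotation(Rz50, diag(3)), Rz50)
  expect_equal(relative_rotation(Rz50, Rz30), axis_rotmat(c(0, 0, 1), 20),
               tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    R <- quat_to_rotmat(random_unit_quats(1)[1, ])
    R0 <- quat_to_rotmat(random_unit_quats(1)[1, ])
    expect_lt(max(abs(R0 %*% relative_rotation(R, R0) - R)), 1e-9)
  }
  expect_error(relative_rotation(matrix(1:9 / 2, 3), diag(3)), "invalid rotation")
})

test_that("point rotation preserves norms and rejects degenerate input", {
  expect_equal(rotate_point(diag(3), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(rotate_point(axis_rotmat(c(1, 0, 0), 90), c(0, 0, 1)),
               c(0, -1, 0), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    R <- quat_to_rotmat(random_unit_quats(1)[1, ])
    p <- stats::rnorm(3)
    expect_equal(sqrt(sum(rotate_point(R, p)^2)), sqrt(sum(p^2)),
                 tolerance = 1e-9)
  }
  expect_error(rotate_point(diag(3), c(0, 0, 0)), "degenerate direction")
})

test_that("spherical conversion hits the convention anchors and round-trips", {
  expect_equal(to_spherical(c(0, 0, 1))$beta, 0)
  p <- to_spherical(c(1, 0, 0))
  expect_equal(p$beta, 90)
  expect_equal(p$alpha, 0)
  for (k in c(0.5, 1, 7)) {
    s <- to_spherical(c(1, 1, sqrt(2)) * k)
    expect_equal(s$r, 2 * k, tolerance = 1e-12)
    expect_equal(s$beta, 45, tolerance = 1e-12)
    expect_equal(s$alpha, 45, tolerance = 1e-12)
  }
  expect_error(to_spherical(c(0, 0, 0)), "degenerate")

  grid <- expand.grid(alpha = seq(-175, 180, by = 5), beta = seq(5, 175, by = 5))
  back <- to_spherical(spherical_to_cartesian(grid$alpha, grid$beta))
  expect_lt(max(abs(wrap180(back$alpha - grid$alpha))), 1e-9)
  expect_lt(max(abs(back$beta - grid$beta)), 1e-9)
})

test_that("stream conversion equals the composed per-sample chain", {
  set.seed(11)
  Q <- random_unit_quats(50)
  st <- data.frame(t = seq_len(50) / 100, qw = Q[, 1], qx = Q[, 2],
                   qy = Q[, 3], qz = Q[, 4])
  ref <- Q[1, ]
  poses <- stream_to_poses(st, reference = ref)
  R0 <- quat_to_rotmat(ref)
  for (i in c(1, 17, 50)) {
    Rrel <- relative_rotation(quat_to_rotmat(Q[i, ]), R0)
    expected <- rotate_point(Rrel, c(0, 0, 1))
    # compare as direction vectors: azimuth is undefined at zero elevation
    got <- as.numeric(spherical_to_cartesian(poses$alpha[i], poses$beta[i]))
    expect_equal(got, expected, tolerance = 1e-9)
  }
  expect_true(all(poses$beta >= 0 & poses$beta <= 180))
  expect_true(all(poses$alpha > -180 & poses$alpha <= 180))
  expect_true(all(poses$r > 0))
})

test_that("a stream holding the reference pose stays at zero elevation", {
  st <- data.frame(t = 0.01, qw = 1, qx = 0, qy = 0, qz = 0)
  poses <- stream_to_poses(st)
  expect_equal(poses$beta, 0)
})

test_that("commanded gimbal angles are recovered exactly in the noise-free case", {
  cmd <- expand.grid(yaw = c(-150, -60, 0, 45, 90, 179), pitch = c(10, 45, 90, 150))
  st <- angles_to_stream(cmd$yaw, cmd$pitch)
  poses <- stream_to_poses(st, reference = c(1, 0, 0, 0))
  expect_lt(max(abs(wrap180(poses$alpha - cmd$yaw))), 1e-6)
  expect_lt(max(abs(poses$beta - cmd$pitch)), 1e-6)
})

test_that("stream validation rejects empty and non-monotone input", {
  expect_error(stream_to_poses(data.frame(t = numeric(), qw = numeric(),
                                          qx = numeric(), qy = numeric(),
                                          qz = numeric())), "empty")
  st <- data.frame(t = c(0.01, 0.03, 0.02), qw = 1, qx = 0, qy = 0, qz = 0)
  expect_error(stream_to_poses(st), "non-monotone")
  st2 <- data.frame(t = c(0.01, 0.02), qw = c(1, 0.9), qx = 0, qy = 0, qz = 0)
  expect_error(stream_to_poses(st2), "t = 0.02")
})

test_that("great-circle sweeps through beta = 90 and alpha = 180 are continuous", {
  step_angle <- function(poses) {
    v <- spherical_to_cartesian(poses$alpha, poses$beta)
    dots <- rowSums(v[-1, , drop = FALSE] * v[-nrow(v), , drop = FALSE])
    acos(pmin(pmax(dots, -1), 1)) * 180 / pi
  }
  # meridian sweep crossing the horizontal (beta = 90)
  beta <- seq(1, 179, by = 1)
  poses <- stream_to_poses(angles_to_stream(rep(170, length(beta)), beta),
                           reference = c(1, 0, 0, 0))
  expect_lt(max(step_angle(poses)), 1 + 1e-6)
  # equatorial sweep crossing alpha = +/-180
  alpha <- seq(90, 270, by = 1)  # wraps through the posterior seam
  poses2 <- stream_to_poses(angles_to_stream(alpha, rep(90, length(alpha))),
                            reference = c(1, 0, 0, 0))
  expect_lt(max(step_angle(poses2)), 1 + 1e-6)
  expect_lt(max(abs(wrap180(poses2$alpha - alpha))), 1e-6)
})
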