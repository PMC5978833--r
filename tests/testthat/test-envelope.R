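# Workspace envelope extraction, surface area, region partition, per-plane
# maxima, and repeatability statistics.

test_that("envelope records the per-bin maximum elevation", {
  one <- build_envelope(data.frame(alpha = 0, beta = 120), bin_width = 10)
  expect_equal(sum(!is.na(one$beta_max)), 1L)
  expect_equal(one$beta_max[!is.na(one$beta_max)], 120)

  # revisiting a bin at lower elevation never decreases beta_max
  two <- build_envelope(data.frame(alpha = c(2, 3), beta = c(120, 40)),
                        bin_width = 10)
  expect_equal(two$beta_max[!is.na(two$beta_max)], 120)

  expect_error(build_envelope(data.frame(alpha = numeric(), beta = numeric())),
               "empty")
  expect_error(build_envelope(data.frame(alpha = 0, beta = 1), bin_width = 7),
               "divide")
})

test_that("a densely traced profile is recovered to within discretization", {
  B <- function(a) 90 + 60 * cos(a * pi / 180)
  alpha <- seq(-179.99, 180, by = 0.01)
  env <- build_envelope(data.frame(alpha = alpha, beta = B(alpha)), bin_width = 5)
  expect_false(anyNA(env$beta_max))
  # exact against a per-bin max oracle on the same sampling
  idx <- ceiling((alpha + 180) / 5)
  oracle <- as.numeric(tapply(B(alpha), idx, max))
  expect_equal(env$beta_max, oracle, tolerance = 1e-9)
  # and close to the profile at bin centers (bounded by slope * bin_width/2)
  expect_lt(max(abs(env$beta_max - B(env$bin_centers))), 5)
})

test_that("surface area matches closed forms and is monotone", {
  flat <- build_envelope(data.frame(alpha = seq(-179.5, 180, by = 1),
                                    beta = 90), bin_width = 5)
  expect_equal(surface_area(flat, "planar"), 32400)

  full <- build_envelope(data.frame(alpha = seq(-179.5, 180, by = 1),
                                    beta = 180), bin_width = 5)
  expect_equal(surface_area(full, "solid_angle"), 4 * pi * (180 / pi)^2,
               tolerance = 1e-9)
  expect_equal(4 * pi * (180 / pi)^2, 41252.96, tolerance = 1e-7)

  set.seed(21)
  env <- build_envelope(data.frame(alpha = seq(-177.5, 180, by = 5),
                                   beta = stats::runif(72, 20, 160)),
                        bin_width = 5)
  for (mode in c("planar", "solid_angle")) {
    a0 <- surface_area(env, mode)
    env2 <- env
    k <- which(!is.na(env2$beta_max))[10]
    env2$beta_max[k] <- min(env2$beta_max[k] + 15, 180)
    expect_gte(surface_area(env2, mode), a0)
    expect_lte(surface_area(env, "solid_angle"), 41252.97)
  }
})

test_that("solid-angle area agrees with a Monte-Carlo sphere oracle", {
  set.seed(99)
  env <- build_envelope(data.frame(alpha = seq(-177.5, 180, by = 5),
                                   beta = stats::runif(72, 20, 160)),
                        bin_width = 5)
  mc <- mc_solid_angle_area(env, n = 1e6)
  expect_equal(surface_area(env, "solid_angle"), mc,
               tolerance = 0.01)
})

test_that("region classification is a total partition matching the labels", {
  part <- region_partition()
  # lower medial just below the split
  expect_equal(as.character(classify_region(-90, part$elevation_split - 1, part)), "I")
  # higher posterior just above the split
  expect_equal(as.character(classify_region(150, part$elevation_split + 1, part)), "VI")
  expect_equal(as.character(classify_region(45, 120, part)), "IV")

  grid <- expand.grid(alpha = seq(-179, 180, by = 1), beta = seq(0, 180, by = 1))
  lab <- classify_region(grid$alpha, grid$beta, part)
  expect_false(anyNA(lab))
  expect_equal(sum(table(lab)), nrow(grid))
})

test_that("plane maxima pick the right windows and mark unreached planes NA", {
  # pure abduction arc: azimuth fixed at 90
  arc <- data.frame(t = 1:150 / 100, alpha = 90, beta = seq(1, 150, by = 1))
  pm <- plane_maxima(arc)
  expect_equal(pm$max_abduction, 150)
  expect_true(is.na(pm$max_flexion))
  expect_true(is.na(pm$max_extension))

  # anterior-only low envelope: no posterior, nothing near horizontal
  low <- data.frame(t = 1:100 / 100, alpha = seq(-60, 60, length.out = 100),
                    beta = 65)
  pml <- plane_maxima(low)
  expect_true(is.na(pml$max_extension))
  expect_true(is.na(pml$max_horizontal_abduction))
  expect_equal(pml$max_flexion, 65)

  # horizontal span across the posterior seam uses the unwrapped axis
  a <- seq(100, 250, by = 1)  # continuous sweep through alpha = 180
  seam <- data.frame(t = seq_along(a) / 100, alpha = wrap180(a), beta = 90)
  expect_equal(plane_maxima(seam)$max_horizontal_abduction, 150)
})

test_that("unwrapping reconstructs a continuous azimuth axis", {
  a <- c(170, 175, 180, -175, -170)
  expect_equal(unwrap_degrees(a), c(170, 175, 180, 185, 190))
  expect_equal(unwrap_degrees(c(5)), 5)
})

test_that("coefficient of variation follows sd/mean and tracks injected noise", {
  expect_equal(cv_across_trials(c(10, 10, 10)), 0)
  expect_equal(cv_across_trials(c(9, 10, 11)), 10.0)
  expect_error(cv_across_trials(5), "at least 2")
  expect_error(cv_across_trials(c(-1, 1)), "zero mean")

  # three repeats with 2% multiplicative area noise -> CV near 2%
  set.seed(5)
  base <- 27000
  cvs <- replicate(100, cv_across_trials(base * (1 + stats::rnorm(3, 0, 0.02))))
  expect_gt(mean(cvs), 1.2)
  expect_lt(mean(cvs), 2.8)
})
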