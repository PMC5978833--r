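# Hardware stand-in: generates quaternion + EMG CSV streams for (a) the
# expanding-circuit maximal-workspace protocol and (b) a servo-driven gimbal
# rig with a known pitch/yaw schedule, used to validate the orientation chain.

#' Quaternion realizing a commanded spherical pose
#'
#' Returns the shortest-arc rotation that carries the neutral arm direction
#' (0, 0, 1) to azimuth `alpha`, elevation `beta`: a rotation by `beta`
#' about the horizontal axis `(-sin alpha, cos alpha, 0)`. The axial-rotation
#' degree of freedom, which the spherical description deliberately ignores,
#' is fixed by this shortest-arc choice. Vectorized over `alpha`/`beta`.
#'
#' @param alpha azimuth, degrees.
#' @param beta elevation, degrees, in [0, 180].
#' @return a data frame with columns `qw, qx, qy, qz` (canonical `qw >= 0`).
#' @export
spherical_to_quaternion <- function(alpha, beta) {
  h <- beta * pi / 360          # half-angle in radians
  a <- alpha * pi / 180
  data.frame(qw = cos(h), qx = -sin(h) * sin(a), qy = sin(h) * cos(a),
             qz = rep(0, length(h)))
}

#' Smooth maximal-elevation profile of a healthy shoulder
#'
#' A periodic spline through azimuth/elevation anchors: peak elevation near
#' 150 deg anteriorly (flexion), about 141 deg in the abduction plane, and
#' roughly 58 deg posteriorly. A plausible healthy profile for exercising
#' the pipeline, not a reproduction of any subject's data.
#'
#' @return a function `B(alpha)` giving maximal elevation in degrees for
#'   azimuth in degrees (any real value; 360-periodic).
#' @export
healthy_envelope <- function() {
  anchors_a <- c(-180, -135, -90, -45, 0, 45, 90, 135, 180)
  anchors_b <- c(58, 70, 100, 130, 150, 152, 141, 80, 58)
  f <- stats::splinefun(anchors_a, anchors_b, method = "periodic")
  function(alpha) pmin(pmax(f(wrap180(alpha)), 0), 180)
}

#' Restricted envelope emulating a frozen shoulder
#'
#' The healthy profile scaled down and capped at `cap` degrees of elevation;
#' combined with a restricted azimuth sweep (see [motion_scenario()] preset
#' `"frozen"`) this reproduces the qualitative picture of adhesive
#' capsulitis: no near-horizontal reach, no posterior reach.
#'
#' @param cap elevation ceiling in degrees (default 70).
#' @param scale multiplier on the healthy profile (default 0.8).
#' @return a function `B(alpha)` in degrees.
#' @export
frozen_envelope <- function(cap = 70, scale = 0.8) {
  healthy <- healthy_envelope()
  function(alpha) pmin(healthy(alpha) * scale, cap)
}

#' Describe an arm-circuit motion scenario
#'
#' The measurement protocol: starting from rest, the subject traces the
#' envelope in `n_circuits` consecutive circuits of increasing size, circuit
#' k sweeping azimuth across `alpha_range` (alternating direction, as a
#' subject comfortably reverses) with elevation tracking
#' `circuit_fractions[k] * B(alpha)`.
#'
#' @param envelope_function maximal elevation `B(alpha)` in degrees.
#' @param n_circuits number of circuits (protocol: 4).
#' @param circuit_fractions strictly increasing fractions of `B` per
#'   circuit, last = 1.
#' @param sample_rate Hz (default 100, the device's streaming rate).
#' @param duration total trial length in seconds (default 60).
#' @param orientation_noise_sd angular jitter SD in degrees, added
#'   independently to azimuth and elevation (default 0.5, a typical
#'   consumer-IMU static error).
#' @param alpha_range azimuth sweep limits in degrees.
#' @return an object of class `motion_scenario`.
#' @export
motion_scenario <- function(envelope_function = healthy_envelope(),
                            n_circuits = 4,
                            circuit_fractions = c(0.25, 0.5, 0.75, 1),
                            sample_rate = 100,
                            duration = 60,
                            orientation_noise_sd = 0.5,
                            alpha_range = c(-179, 180)) {
  stopifnot(is.function(envelope_function),
            length(circuit_fractions) == n_circuits,
            all(diff(circuit_fractions) > 0),
            abs(circuit_fractions[n_circuits] - 1) < 1e-12,
            orientation_noise_sd >= 0,
            duration > 2 + 0.5 * n_circuits)
  structure(list(envelope_function = envelope_function, n_circuits = n_circuits,
                 circuit_fractions = circuit_fractions, sample_rate = sample_rate,
                 duration = duration, orientation_noise_sd = orientation_noise_sd,
                 alpha_range = alpha_range),
            class = "motion_scenario")
}

#' Scenario presets
#'
#' `"healthy"`: full-azimuth circuits over the healthy envelope.
#' `"frozen"`: circuits confined to the anterior half-space (azimuth
#' -115..115 deg) over the capped frozen-shoulder envelope, so posterior and
#' near-horizontal planes are never visited.
#'
#' @param preset preset name.
#' @param ... overrides passed to [motion_scenario()].
#' @return a `motion_scenario`.
#' @export
scenario_preset <- function(preset = c("healthy", "frozen"), ...) {
  preset <- match.arg(preset)
  if (preset == "healthy") {
    motion_scenario(...)
  } else {
    motion_scenario(envelope_function = frozen_envelope(),
                    alpha_range = c(-115, 115), ...)
  }
}

#' Elevation-dependent deltoid EMG surrogate
#'
#' Per-channel activation `a(alpha, beta) = (beta/180)^1.2 *
#' (0.55 + 0.45 cos(alpha - mu))` with preferred azimuth `mu` of 0, 90 and
#' 160 degrees for the anterior, middle and posterior sections — strictly
#' increasing in elevation at any azimuth, which mirrors the empirical
#' pattern of deltoid recruitment during arm raising.
#'
#' @param noise_sd multiplicative noise SD (default 0.1).
#' @param baseline resting activation level in [0, 1) (default 0.05).
#' @return an object of class `emg_surrogate`: list of per-channel
#'   activation functions plus noise parameters.
#' @export
emg_surrogate <- function(noise_sd = 0.1, baseline = 0.05) {
  mus <- c(emg_ant = 0, emg_mid = 90, emg_post = 160)
  funs <- lapply(mus, function(mu) {
    force(mu)
    function(alpha, beta) {
      (pmin(pmax(beta, 0), 180) / 180)^1.2 *
        (0.55 + 0.45 * cos((alpha - mu) * pi / 180))
    }
  })
  structure(list(activation = funs, noise_sd = noise_sd, baseline = baseline),
            class = "emg_surrogate")
}

# Ideal (alpha, beta) trajectory for a scenario, sampled at its rate.
# Segments: 1 s rest, then per circuit a 0.5 s elevation ramp at the turn
# azimuth followed by a constant-speed azimuth sweep, finally a 1 s lowering.
scenario_trajectory <- function(scn) {
  n <- scn$n_circuits
  B <- scn$envelope_function
  f <- scn$circuit_fractions
  sweep_dur <- (scn$duration - 2 - 0.5 * n) / n
  a_lo <- scn$alpha_range[1]; a_hi <- scn$alpha_range[2]

  segs <- list(list(dur = 1, type = "rest"))
  at <- a_lo
  beta_prev <- 0
  for (k in seq_len(n)) {
    target <- f[k] * B(at)
    segs[[length(segs) + 1L]] <- list(dur = 0.5, type = "ramp", alpha = at,
                                      b0 = beta_prev, b1 = target)
    a_to <- if (at == a_lo) a_hi else a_lo
    segs[[length(segs) + 1L]] <- list(dur = sweep_dur, type = "sweep",
                                      a0 = at, a1 = a_to, frac = f[k])
    beta_prev <- f[k] * B(a_to)
    at <- a_to
  }
  segs[[length(segs) + 1L]] <- list(dur = 1, type = "ramp", alpha = at,
                                    b0 = beta_prev, b1 = 0)

  tt <- seq(0, scn$duration - 1 / scn$sample_rate, by = 1 / scn$sample_rate)
  ends <- cumsum(vapply(segs, `[[`, numeric(1), "dur"))
  starts <- c(0, ends[-length(ends)])
  alpha <- numeric(length(tt)); beta <- numeric(length(tt))
  for (i in seq_along(segs)) {
    sel <- tt >= starts[i] & tt < ends[i]
    if (!any(sel)) next
    s <- (tt[sel] - starts[i]) / segs[[i]]$dur
    sg <- segs[[i]]
    if (sg$type == "rest") {
      alpha[sel] <- a_lo; beta[sel] <- 0
    } else if (sg$type == "ramp") {
      alpha[sel] <- sg$alpha
      beta[sel] <- sg$b0 + s * (sg$b1 - sg$b0)
    } else {
      av <- sg$a0 + s * (sg$a1 - sg$a0)
      alpha[sel] <- av
      beta[sel] <- sg$frac * B(av)
    }
  }
  data.frame(t = tt, alpha = alpha, beta = beta)
}

#' Simulate a full assessment trial
#'
#' Generates the quaternion + EMG stream a subject performing the
#' expanding-circuit protocol would produce: the ideal trajectory from
#' [motion_scenario()], Gaussian angular jitter applied in (azimuth,
#' elevation) space, quaternions via [spherical_to_quaternion()], and EMG
#' channels `100 * (baseline + (1 - baseline) * a(alpha, beta)) *
#' (1 + noise)`, clipped at 0. Deterministic for a fixed seed.
#'
#' @param scn a [motion_scenario()].
#' @param emg an [emg_surrogate()], or `NULL` for no EMG columns.
#' @param seed integer seed for the jitter and EMG noise.
#' @return an object of class `sim_trial`: list with `stream` (data frame
#'   `t, qw, qx, qy, qz[, emg_*]`), `truth` (ideal `t, alpha, beta`) and the
#'   scenario.
#' @export
simulate_trial <- function(scn = motion_scenario(), emg = emg_surrogate(),
                           seed = 1L) {
  stopifnot(inherits(scn, "motion_scenario"))
  set.seed(as.integer(seed))
  traj <- scenario_trajectory(scn)
  nsamp <- nrow(traj)

  sd <- scn$orientation_noise_sd
  alpha_meas <- traj$alpha + if (sd > 0) stats::rnorm(nsamp, 0, sd) else 0
  beta_meas <- pmin(pmax(traj$beta + if (sd > 0) stats::rnorm(nsamp, 0, sd) else 0,
                         0), 180)
  q <- spherical_to_quaternion(alpha_meas, beta_meas)
  stream <- data.frame(t = traj$t, q)

  if (!is.null(emg)) {
    stopifnot(inherits(emg, "emg_surrogate"))
    for (ch in names(emg$activation)) {
      act <- emg$baseline +
        (1 - emg$baseline) * emg$activation[[ch]](traj$alpha, traj$beta)
      noise <- if (emg$noise_sd > 0) stats::rnorm(nsamp, 0, emg$noise_sd) else 0
      stream[[ch]] <- pmax(100 * act * (1 + noise), 0)
    }
  }
  structure(list(stream = stream, truth = traj, scenario = scn),
            class = "sim_trial")
}

#' Describe a gimbal test program
#'
#' @param waypoints data frame with columns `pitch`, `yaw` (degrees, within
#'   the mechanical range [-180, 180]) and `dwell` (seconds to hold at the
#'   waypoint).
#' @param slew_rate servo slew rate in degrees/second.
#' @return an object of class `gimbal_program`.
#' @export
gimbal_program <- function(waypoints, slew_rate = 60) {
  stopifnot(is.data.frame(waypoints),
            all(c("pitch", "yaw", "dwell") %in% names(waypoints)),
            all(abs(waypoints$pitch) <= 180), all(abs(waypoints$yaw) <= 180),
            slew_rate > 0)
  structure(list(waypoints = waypoints, slew_rate = slew_rate),
            class = "gimbal_program")
}

#' Default gimbal validation program
#'
#' Full elevation sweeps (0 -> 160 -> 0 deg pitch) in four abduction planes
#' (yaw 0, 45, 90, 135 deg) followed by a horizontal-abduction sweep at
#' 90 deg pitch from yaw -60 to 140 deg.
#'
#' @param slew_rate degrees/second (default 60).
#' @return a [gimbal_program()].
#' @export
default_gimbal_program <- function(slew_rate = 60) {
  wp <- do.call(rbind, lapply(c(0, 45, 90, 135), function(plane) {
    data.frame(pitch = c(160, 0), yaw = plane, dwell = 0.3)
  }))
  wp <- rbind(wp,
              data.frame(pitch = 90, yaw = -60, dwell = 0.3),
              data.frame(pitch = 90, yaw = 140, dwell = 0.3),
              data.frame(pitch = 0, yaw = 0, dwell = 0.3))
  gimbal_program(wp, slew_rate = slew_rate)
}

#' Simulate the servo-driven gimbal rig
#'
#' Moves linearly in (pitch, yaw) between waypoints at the slew rate,
#' starting from (0, 0), holding each waypoint for its dwell time, and
#' emits the quaternion stream the mounted IMU would report, with Gaussian
#' angular jitter in (pitch, yaw) space. The commanded angles per sample are
#' returned as ground truth.
#'
#' @param prog a [gimbal_program()].
#' @param noise_sd angular jitter SD in degrees (0 for an ideal sensor).
#' @param sample_rate Hz (default 100).
#' @param seed integer seed.
#' @return an object of class `sim_gimbal`: list with `stream`
#'   (`t, qw, qx, qy, qz`) and `truth` (`t, pitch, yaw`).
#' @export
simulate_gimbal <- function(prog = default_gimbal_program(), noise_sd = 0.3,
                            sample_rate = 100, seed = 1L) {
  stopifnot(inherits(prog, "gimbal_program"), noise_sd >= 0)
  set.seed(as.integer(seed))
  wp <- rbind(data.frame(pitch = 0, yaw = 0, dwell = 0.5), prog$waypoints)
  pitch <- numeric(0); yaw <- numeric(0)
  dt <- 1 / sample_rate
  for (i in seq_len(nrow(wp))) {
    if (i > 1L) {
      travel <- max(abs(wp$pitch[i] - wp$pitch[i - 1]),
                    abs(wp$yaw[i] - wp$yaw[i - 1])) / prog$slew_rate
      nmove <- max(ceiling(travel * sample_rate), 1L)
      s <- seq_len(nmove) / nmove
      pitch <- c(pitch, wp$pitch[i - 1] + s * (wp$pitch[i] - wp$pitch[i - 1]))
      yaw <- c(yaw, wp$yaw[i - 1] + s * (wp$yaw[i] - wp$yaw[i - 1]))
    }
    nhold <- max(round(wp$dwell[i] * sample_rate), 1L)
    pitch <- c(pitch, rep(wp$pitch[i], nhold))
    yaw <- c(yaw, rep(wp$yaw[i], nhold))
  }
  tt <- (seq_along(pitch) - 1L) * dt
  pm <- pmin(pmax(pitch + if (noise_sd > 0) stats::rnorm(length(pitch), 0, noise_sd) else 0,
                  0), 180)
  ym <- yaw + if (noise_sd > 0) stats::rnorm(length(yaw), 0, noise_sd) else 0
  q <- spherical_to_quaternion(ym, pm)
  structure(list(stream = data.frame(t = tt, q),
                 truth = data.frame(t = tt, pitch = pitch, yaw = yaw)),
            class = "sim_gimbal")
}

#' Validate the orientation chain against gimbal ground truth
#'
#' Runs [stream_to_poses()] on the simulated IMU stream (reference = the
#' neutral identity orientation) and compares recovered elevation/azimuth
#' with the commanded pitch/yaw. Azimuth error is evaluated only where
#' commanded elevation is at least `min_elevation` degrees, because azimuth
#' is undefined at zero elevation and ill-conditioned near it. The pass
#' thresholds default to the bench maxima established for the physical rig:
#' 3 degrees elevation, 2 degrees azimuth.
#'
#' @param sim a [simulate_gimbal()] result.
#' @param elevation_tol,azimuth_tol pass thresholds in degrees.
#' @param min_elevation commanded-elevation floor for azimuth comparison.
#' @return a list with `max_elevation_error`, `max_azimuth_error` (degrees),
#'   `pass` (logical), the thresholds, and `n` samples compared.
#' @export
validate_gimbal <- function(sim, elevation_tol = 3, azimuth_tol = 2,
                            min_elevation = 15) {
  stopifnot(inherits(sim, "sim_gimbal"))
  poses <- stream_to_poses(sim$stream, reference = c(1, 0, 0, 0))
  elev_err <- max(abs(poses$beta - sim$truth$pitch))
  sel <- sim$truth$pitch >= min_elevation
  az_err <- if (any(sel)) {
    max(abs(wrap180(poses$alpha[sel] - sim$truth$yaw[sel])))
  } else NA_real_
  list(max_elevation_error = elev_err,
       max_azimuth_error = az_err,
       pass = elev_err <= elevation_tol && isTRUE(az_err <= azimuth_tol),
       elevation_tol = elevation_tol, azimuth_tol = azimuth_tol,
       n = nrow(poses))
}
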