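# Reachable-workspace envelope: per-azimuth-bin maximal elevation, its
# surface area, the six-region ROM partition, per-plane maxima, and
# trial-to-trial repeatability.

#' Build the reachable-workspace envelope from a pose sequence
#'
#' Bins azimuth over (-180, 180] and records the maximal observed elevation
#' per bin. Unvisited bins are `NA`; they contribute no area (no
#' interpolation by default — see [surface_area()]).
#'
#' @param poses data frame with columns `alpha`, `beta` (degrees), e.g. from
#'   [stream_to_poses()].
#' @param bin_width azimuth bin width in degrees; must divide 360.
#' @return an object of class `envelope_profile`: a list with `bin_width`,
#'   `bin_centers` and `beta_max` (NA where unvisited).
#' @export
build_envelope <- function(poses, bin_width = 5) {
  if (!is.data.frame(poses) || nrow(poses) == 0L) stop("empty pose sequence")
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  nb <- as.integer(360 / bin_width)
  a <- wrap180(poses$alpha)
  idx <- ceiling((a + 180) / bin_width)
  idx[idx < 1L] <- 1L   # alpha exactly -180 wraps to +180 via wrap180; guard anyway
  beta_max <- rep(NA_real_, nb)
  agg <- tapply(poses$beta, idx, max)
  beta_max[as.integer(names(agg))] <- as.numeric(agg)
  structure(list(
    bin_width = bin_width,
    bin_centers = seq(-180 + bin_width / 2, 180 - bin_width / 2, by = bin_width),
    beta_max = beta_max
  ), class = "envelope_profile")
}

#' @export
print.envelope_profile <- function(x, ...) {
  vis <- sum(!is.na(x$beta_max))
  cat(sprintf("Reachable-workspace envelope: %d x %g deg azimuth bins, %d visited\n",
              length(x$beta_max), x$bin_width, vis))
  if (vis > 0) {
    cat(sprintf("  beta_max range: %.1f to %.1f deg; planar area %.0f deg^2\n",
                min(x$beta_max, na.rm = TRUE), max(x$beta_max, na.rm = TRUE),
                surface_area(x, "planar")))
  }
  invisible(x)
}

#' Envelope surface area in square degrees
#'
#' Two definitions are supported. `planar` (default) integrates the envelope
#' in the azimuth–elevation chart: \eqn{\sum_{bins} \beta_{max} \cdot w}.
#' `solid_angle` measures the true spherical area swept under the envelope,
#' \eqn{\sum_{bins} w_{rad} (1 - \cos\beta_{max})} steradians, converted to
#' square degrees by \eqn{(180/\pi)^2}; a full sphere is 41252.96 deg^2.
#'
#' @param env an `envelope_profile`.
#' @param mode `"planar"` or `"solid_angle"`.
#' @return area in square degrees.
#' @export
surface_area <- function(env, mode = c("planar", "solid_angle")) {
  mode <- match.arg(mode)
  stopifnot(inherits(env, "envelope_profile"))
  b <- env$beta_max[!is.na(env$beta_max)]
  if (length(b) == 0L) stop("envelope has no visited bins")
  if (mode == "planar") {
    sum(b * env$bin_width)
  } else {
    w_rad <- env$bin_width * pi / 180
    sum(w_rad * (1 - cos(b * pi / 180))) * (180 / pi)^2
  }
}

#' Define the six-region ROM partition
#'
#' The workspace is split into lower/higher elevation at `elevation_split`
#' and into medial, lateral and posterior azimuth sectors, giving regions
#' I (lower medial), II (higher medial), III (lower lateral), IV (higher
#' lateral), V (lower posterior), VI (higher posterior).
#'
#' @param elevation_split elevation (degrees) separating lower from higher.
#' @param medial,lateral,posterior azimuth sector bounds `c(lo, hi)` in
#'   degrees; together they must tile (-180, 180] without overlap.
#' @return an object of class `region_partition`.
#' @export
region_partition <- function(elevation_split = 90,
                             medial = c(-180, 0),
                             lateral = c(0, 120),
                             posterior = c(120, 180)) {
  stopifnot(elevation_split > 0, elevation_split < 180)
  bounds <- rbind(medial, lateral, posterior)
  if (any(bounds[, 1] >= bounds[, 2])) stop("sector bounds must be increasing")
  span <- sum(bounds[, 2] - bounds[, 1])
  if (abs(span - 360) > 1e-9) stop("azimuth sectors must tile 360 degrees")
  structure(list(elevation_split = elevation_split, medial = medial,
                 lateral = lateral, posterior = posterior),
            class = "region_partition")
}

sector_of <- function(alpha, part) {
  a <- wrap180(alpha)
  s <- rep("medial", length(a))
  s[a >= part$lateral[1] & a < part$lateral[2]] <- "lateral"
  s[a >= part$posterior[1] & a <= part$posterior[2]] <- "posterior"
  s
}

#' Classify poses into ROM regions I–VI
#'
#' "Higher" means elevation at or above the partition's split; the azimuth
#' sector picks medial (I/II), lateral (III/IV) or posterior (V/VI). The
#' classification is total: every valid pose gets exactly one label.
#'
#' @param alpha,beta pose angles in degrees (vectorized).
#' @param part a [region_partition()].
#' @return a factor with levels `I` to `VI`.
#' @export
classify_region <- function(alpha, beta, part = region_partition()) {
  stopifnot(inherits(part, "region_partition"), length(alpha) == length(beta))
  sec <- sector_of(alpha, part)
  hi <- beta >= part$elevation_split
  lab <- ifelse(sec == "medial", ifelse(hi, "II", "I"),
         ifelse(sec == "lateral", ifelse(hi, "IV", "III"),
                ifelse(hi, "VI", "V")))
  factor(lab, levels = c("I", "II", "III", "IV", "V", "VI"))
}

#' Unwrap an azimuth series onto a continuous axis
#'
#' Removes 360-degree jumps by always taking the nearest branch between
#' consecutive samples, so that spans larger than 180 degrees (as arise in
#' horizontal abduction) are measurable.
#'
#' @param a azimuth series in degrees, ordered in time.
#' @return unwrapped series (first element unchanged).
#' @export
unwrap_degrees <- function(a) {
  if (length(a) < 2L) return(a)
  d <- wrap180(diff(a))
  c(a[1], a[1] + cumsum(d))
}

#' Maximal elevation in the standard shoulder planes
#'
#' Flexion is elevation in the anterior plane (azimuth near 0), abduction in
#' the lateral plane (azimuth near 90), extension the maximal elevation
#' anywhere in the posterior sector, and horizontal abduction the azimuthal
#' span covered while the arm is near horizontal (elevation near 90),
#' measured on a continuity-unwrapped azimuth axis and capped at 360.
#' A plane with no qualifying samples yields `NA` — restricted shoulders may
#' genuinely never reach a plane.
#'
#' @param poses data frame with `t`, `alpha`, `beta`.
#' @param plane_tolerance half-width (degrees) of the flexion/abduction
#'   azimuth windows.
#' @param horizontal_band half-width (degrees) of the elevation window
#'   around 90 used for horizontal abduction.
#' @param part region partition supplying the posterior sector.
#' @return an object of class `plane_maxima`: list with `max_flexion`,
#'   `max_abduction`, `max_extension`, `max_horizontal_abduction` (degrees,
#'   `NA` where absent).
#' @export
plane_maxima <- function(poses, plane_tolerance = 10, horizontal_band = 10,
                         part = region_partition()) {
  if (!is.data.frame(poses) || nrow(poses) == 0L) stop("empty pose sequence")
  a <- wrap180(poses$alpha)
  b <- poses$beta
  max_or_na <- function(x) if (length(x)) max(x) else NA_real_
  flex <- max_or_na(b[abs(a) <= plane_tolerance])
  abd  <- max_or_na(b[abs(a - 90) <= plane_tolerance])
  ext  <- max_or_na(b[sector_of(a, part) == "posterior"])
  horiz <- NA_real_
  sel <- abs(b - 90) <= horizontal_band
  if (any(sel)) {
    ua <- unwrap_degrees(a)[sel]
    horiz <- min(max(ua) - min(ua), 360)
  }
  structure(list(max_flexion = flex, max_abduction = abd,
                 max_extension = ext, max_horizontal_abduction = horiz),
            class = "plane_maxima")
}

#' Coefficient of variation across repeat trials
#'
#' @param values at least two finite per-trial scalars with nonzero mean.
#' @return `100 * sd(values) / mean(values)` (sample SD, n-1 denominator),
#'   in percent.
#' @export
cv_across_trials <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values) || any(!is.finite(values))) {
    stop("need at least 2 finite values to compute a CV")
  }
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  100 * stats::sd(values) / m
}
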