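# Stream CSV and analysis-configuration I/O.
#
# Stream dialect: one row per sample, header required, UTF-8, decimal point:
#   t,qw,qx,qy,qz[,emg_ant,emg_mid,emg_post]   (any subset of EMG columns)

#' Read a quaternion + EMG stream CSV
#'
#' @param path file path.
#' @return a data frame with columns `t, qw, qx, qy, qz` and any EMG
#'   channels present.
#' @export
read_stream_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("t", "qw", "qx", "qy", "qz")
  if (!all(need %in% names(df))) {
    stop(sprintf("stream CSV must have columns %s", paste(need, collapse = ", ")))
  }
  df
}

#' Write a stream CSV with fixed formatting
#'
#' Numbers are printed with a fixed number of decimals so that the same
#' stream always serializes to byte-identical output.
#'
#' @param stream stream data frame.
#' @param path output path.
#' @param digits decimal places (default 6).
#' @return `path`, invisibly.
#' @export
write_stream_csv <- function(stream, path, digits = 6) {
  cols <- names(stream)
  fmt <- paste0("%.", digits, "f")
  body <- do.call(paste, c(lapply(stream, function(x) sprintf(fmt, x)), sep = ","))
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' Default analysis configuration
#'
#' All tunable parameters of the analysis chain, with their defaults:
#' azimuth bin width 5 deg, planar area mode, 10 deg plane tolerance and
#' horizontal band, 90 deg lower/higher elevation split, default azimuth
#' sectors, 0.1 s RMS window at 100 Hz, 10 deg EMG map cells, arm direction
#' (0, 0, 1), reference pose taken from the first sample.
#'
#' @return a named list.
#' @export
default_config <- function() {
  list(
    bin_width = 5,
    area_mode = "planar",
    plane_tolerance = 10,
    horizontal_band = 10,
    elevation_split = 90,
    sectors = list(medial = c(-180, 0), lateral = c(0, 120), posterior = c(120, 180)),
    rms_window = 0.1,
    sample_rate = 100,
    emg_cell = 10,
    arm_direction = c(0, 0, 1),
    reference = "first",
    quaternion_tolerance = 1e-3
  )
}

#' Read an analysis configuration from JSON
#'
#' Unknown keys are rejected; missing keys fall back to [default_config()].
#' `reference` may be the string `"first"` or a 4-element quaternion.
#'
#' @param path JSON file path, or `NULL` for the defaults.
#' @return a validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(user)] <- user
  if (!identical(cfg$reference, "first")) {
    cfg$reference <- check_unit_quaternion(cfg$reference,
                                           tol = cfg$quaternion_tolerance)
  }
  if (!cfg$area_mode %in% c("planar", "solid_angle")) {
    stop("area_mode must be 'planar' or 'solid_angle'")
  }
  cfg
}
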