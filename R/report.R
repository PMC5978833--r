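# Trial analysis driver, per-trial summaries, cohort statistics and group
# comparisons.

#' Analyze one assessment stream end to end
#'
#' Runs the complete chain on a quaternion (+ optional EMG) stream: spherical
#' poses, workspace envelope and surface area, per-plane maxima, region
#' occupancy, and — when EMG channels are present — the RMS/%MVC chain,
#' workspace EMG map and per-region EMG summary.
#'
#' @param stream stream data frame (see [read_stream_csv()]).
#' @param config configuration list from [default_config()]/[read_config()].
#' @return an object of class `trial_analysis`: list with `poses`,
#'   `envelope`, `surface_area`, `area_mode`, `plane_maxima`,
#'   `region_counts`, and (if EMG present) `emg` (%MVC series), `emg_map`,
#'   `region_emg`.
#' @export
analyze_stream <- function(stream, config = default_config()) {
  part <- region_partition(elevation_split = config$elevation_split,
                           medial = config$sectors$medial,
                           lateral = config$sectors$lateral,
                           posterior = config$sectors$posterior)
  reference <- if (identical(config$reference, "first")) NULL else config$reference
  poses <- stream_to_poses(stream, reference = reference,
                           arm_direction = config$arm_direction,
                           tol = config$quaternion_tolerance)
  env <- build_envelope(poses, bin_width = config$bin_width)
  res <- list(
    poses = poses,
    envelope = env,
    surface_area = surface_area(env, config$area_mode),
    area_mode = config$area_mode,
    plane_maxima = plane_maxima(poses, plane_tolerance = config$plane_tolerance,
                                horizontal_band = config$horizontal_band,
                                part = part),
    region_counts = table(classify_region(poses$alpha, poses$beta, part)),
    partition = part
  )

  channels <- intersect(c("emg_ant", "emg_mid", "emg_post"), names(stream))
  if (length(channels)) {
    rate <- if (nrow(stream) > 1) 1 / stats::median(diff(stream$t)) else config$sample_rate
    emg <- data.frame(t = stream$t)
    for (ch in channels) {
      rms <- rectify_rms(stream[[ch]], window = config$rms_window, sample_rate = rate)
      emg[[ch]] <- normalize_mvc(rms)
    }
    res$emg <- emg
    res$emg_map <- emg_workspace_map(poses, emg, cell = config$emg_cell)
    res$region_emg <- region_emg_summary(res$emg_map, part)
  }
  structure(res, class = "trial_analysis")
}

#' Flatten a trial analysis into a one-row summary
#'
#' Assembles the per-trial report row: surface area, per-plane maxima
#' (absent planes as `NA`), region sample counts and per-channel overall
#' mean %MVC.
#'
#' @param analysis a [analyze_stream()] result.
#' @param subject subject identifier.
#' @param trial trial index.
#' @return an object of class `trial_result`: a one-row data frame plus
#'   attributes `region_counts`, `region_emg`.
#' @export
summarize_trial <- function(analysis, subject = NA_character_, trial = NA_integer_) {
  stopifnot(inherits(analysis, "trial_analysis"))
  if (is.null(analysis$envelope)) stop("missing envelope in analysis")
  pm <- analysis$plane_maxima
  row <- data.frame(
    subject = subject, trial = trial,
    surface_area = analysis$surface_area,
    area_mode = analysis$area_mode,
    max_flexion = pm$max_flexion,
    max_abduction = pm$max_abduction,
    max_extension = pm$max_extension,
    max_horizontal_abduction = pm$max_horizontal_abduction,
    stringsAsFactors = FALSE
  )
  for (ch in c("emg_ant", "emg_mid", "emg_post")) {
    row[[paste0(ch, "_mean_pct_mvc")]] <-
      if (!is.null(analysis$emg) && ch %in% names(analysis$emg)) {
        mean(analysis$emg[[ch]])
      } else NA_real_
  }
  structure(row, class = c("trial_result", "data.frame"),
            region_counts = analysis$region_counts,
            region_emg = analysis$region_emg)
}

#' Serialize a trial analysis to JSON
#'
#' Every numeric in the human-readable report is present here too; the
#' output is deterministic for identical inputs.
#'
#' @param analysis a [analyze_stream()] result.
#' @param path output path, or `NULL` to return the JSON string.
#' @return the JSON string, invisibly if written to `path`.
#' @export
write_trial_json <- function(analysis, path = NULL) {
  stopifnot(inherits(analysis, "trial_analysis"))
  env <- analysis$envelope
  obj <- list(
    schema = "shoulderom/trial/v1",
    surface_area_deg2 = analysis$surface_area,
    area_mode = analysis$area_mode,
    plane_maxima = unclass(analysis$plane_maxima),
    region_sample_counts = as.list(analysis$region_counts),
    envelope = list(bin_width = env$bin_width,
                    bin_center = env$bin_centers,
                    beta_max = env$beta_max)
  )
  if (!is.null(analysis$region_emg)) {
    obj$region_emg = analysis$region_emg
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                           dataframe = "columns")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Cohort statistics across subjects
#'
#' Subjects with repeat trials are first reduced to their per-subject mean;
#' group statistics are then the mean and sample standard deviation (n-1
#' denominator) per metric. When a subject has repeats, the per-subject
#' coefficient of variation of `surface_area` (or any metric present) can be
#' obtained with [cv_across_trials()] on the trial-level values.
#'
#' @param trials data frame with columns `subject`, `group` and numeric
#'   metric columns (e.g. rows from [summarize_trial()]).
#' @param metrics metric column names; default: all numeric columns other
#'   than identifiers.
#' @return an object of class `cohort_summary`: data frame with columns
#'   `group`, `metric`, `mean`, `sd`, `n` (subjects with a non-missing
#'   value).
#' @export
summarize_cohort <- function(trials, metrics = NULL) {
  stopifnot(is.data.frame(trials),
            all(c("subject", "group") %in% names(trials)),
            nrow(trials) > 0)
  if (is.null(metrics)) {
    metrics <- names(trials)[vapply(trials, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("trial"))
  }
  # per-subject means across repeat trials
  per_subj <- stats::aggregate(trials[metrics],
                               by = list(subject = trials$subject,
                                         group = trials$group),
                               FUN = function(x) mean(x, na.rm = TRUE))
  out <- do.call(rbind, lapply(split(per_subj, per_subj$group), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- g[[m]]
      v <- v[is.finite(v)]
      n <- length(v)
      if (n == 0L) return(data.frame(group = g$group[1], metric = m,
                                     mean = NA_real_, sd = NA_real_, n = 0L))
      if (n == 1L) {
        warning(sprintf("group '%s', metric '%s': single subject, SD set to 0",
                        g$group[1], m))
      }
      data.frame(group = g$group[1], metric = m, mean = mean(v),
                 sd = if (n > 1) stats::sd(v) else 0, n = n)
    }))
  }))
  rownames(out) <- NULL
  structure(out, class = c("cohort_summary", "data.frame"))
}

#' Compare two cohort summaries metric by metric
#'
#' Reports, per metric, the difference `b - a` of group means and `b` as a
#' percentage of the reference group `a`. No inferential statistics are
#' attached.
#'
#' @param a,b `cohort_summary` objects (single group each, or filtered to
#'   one group); `a` is the reference.
#' @return data frame with columns `metric`, `mean_a`, `mean_b`,
#'   `difference`, `ratio_pct`.
#' @export
compare_groups <- function(a, b) {
  stopifnot(inherits(a, "cohort_summary"), inherits(b, "cohort_summary"))
  if (!setequal(a$metric, b$metric)) stop("metric mismatch between groups")
  b <- b[match(a$metric, b$metric), ]
  data.frame(
    metric = a$metric,
    mean_a = a$mean,
    mean_b = b$mean,
    difference = b$mean - a$mean,
    ratio_pct = 100 * b$mean / a$mean
  )
}

#' Published reference cohort measurements
#'
#' Per-subject reachable-workspace measurements for six healthy shoulders
#' (`h1`–`h6`, group `h`) and one frozen shoulder (`i1`, group `i`):
#' planar surface area (deg^2), repeat-trial coefficient of variation (%),
#' per-plane maxima (deg; `NA` where the subject never reached the plane)
#' and per-deltoid-section mean EMG (%MVC). Shipped as plain CSV in
#' `extdata`.
#'
#' @return a data frame with one row per subject.
#' @export
rom_reference_cohort <- function() {
  path <- system.file("extdata", "rom_reference_cohort.csv",
                      package = "shoulderom", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
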