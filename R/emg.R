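# Surface-EMG processing: rectification + RMS envelope, MVC normalization,
# and binning of muscle activity over the (alpha, beta) workspace.

#' Rectified RMS envelope of a raw EMG signal
#'
#' Computes the root-mean-square of the signal over a centered moving window
#' (truncated at the stream edges), which rectifies and smooths in one step.
#' No additional filtering is applied by default; set `highpass_mean = TRUE`
#' to remove a DC offset by subtracting the signal mean first.
#'
#' @param raw numeric vector, signed raw EMG in arbitrary units.
#' @param window window length in seconds (default 0.1 s, i.e. 10 samples at
#'   100 Hz — standard surface-EMG envelope practice at this rate).
#' @param sample_rate sampling rate in Hz (default 100).
#' @param highpass_mean subtract the signal mean before squaring (default
#'   `FALSE`).
#' @return non-negative RMS envelope, same length as `raw`.
#' @export
rectify_rms <- function(raw, window = 0.1, sample_rate = 100, highpass_mean = FALSE) {
  raw <- as.numeric(raw)
  w <- round(window * sample_rate)
  if (w < 2) stop("RMS window must span at least 2 samples")
  if (isTRUE(highpass_mean)) raw <- raw - mean(raw)
  as.numeric(sqrt(zoo::rollapply(raw^2, width = w, FUN = mean,
                                 partial = TRUE, align = "center")))
}

#' Normalize an RMS envelope to the trial maximum (%MVC)
#'
#' The maximum voluntary contraction reference is the within-trial maximum
#' of the RMS envelope, so the output peaks at exactly 100 for any
#' non-degenerate channel and is invariant to rescaling of the raw signal.
#'
#' @param rms non-negative RMS envelope.
#' @return the envelope as percent of its maximum, in [0, 100].
#' @export
normalize_mvc <- function(rms) {
  rms <- as.numeric(rms)
  if (any(rms < 0)) stop("RMS envelope must be non-negative")
  m <- max(rms)
  if (!is.finite(m) || m == 0) stop("degenerate channel: all-zero RMS envelope")
  100 * rms / m
}

#' Map EMG intensity over the workspace
#'
#' Bins synchronized %MVC samples into an (azimuth, elevation) grid and
#' reports the per-cell mean and sample count per channel. Cells never
#' visited are absent from the output; counts over all cells equal the
#' stream length for every channel.
#'
#' @param poses data frame with `t`, `alpha`, `beta`.
#' @param emg data frame with column `t` plus one numeric %MVC column per
#'   channel; timestamps must match `poses$t` within half a sample interval.
#' @param cell grid cell size in degrees (same for both axes).
#' @return an object of class `emg_map`: long data frame with columns
#'   `alpha_bin`, `beta_bin` (cell centers), `channel`, `mean_pct_mvc`, `n`.
#' @export
emg_workspace_map <- function(poses, emg, cell = 10) {
  stopifnot(is.data.frame(poses), is.data.frame(emg), "t" %in% names(emg))
  if (nrow(poses) != nrow(emg)) stop("poses and EMG streams have different lengths")
  dt <- if (nrow(poses) > 1L) stats::median(diff(poses$t)) else 1
  if (max(abs(poses$t - emg$t)) > dt / 2) {
    stop("timestamp mismatch between poses and EMG beyond half a sample interval")
  }
  channels <- setdiff(names(emg), "t")
  if (length(channels) == 0L) stop("no EMG channels in input")

  a <- wrap180(poses$alpha)
  ai <- pmax(ceiling((a + 180) / cell), 1L)
  bi <- pmax(ceiling(poses$beta / cell), 1L)
  out <- do.call(rbind, lapply(channels, function(ch) {
    v <- emg[[ch]]
    key <- interaction(ai, bi, drop = TRUE)
    data.frame(
      alpha_bin = -180 + (tapply(ai, key, `[`, 1) - 0.5) * cell,
      beta_bin = (tapply(bi, key, `[`, 1) - 0.5) * cell,
      channel = ch,
      mean_pct_mvc = as.numeric(tapply(v, key, mean)),
      n = as.integer(tapply(v, key, length)),
      row.names = NULL
    )
  }))
  structure(out, class = c("emg_map", "data.frame"), cell = cell)
}

#' Per-region EMG summary
#'
#' Aggregates a workspace EMG map over the six ROM regions with
#' sample-count weighting, and reports the most active region per channel.
#'
#' @param map an [emg_workspace_map()] result.
#' @param part a [region_partition()].
#' @return a data frame with columns `region`, `channel`, `mean_pct_mvc`,
#'   `n` (regions never visited have `n = 0` and `NA` mean); attribute
#'   `most_active` names the arg-max region per channel.
#' @export
region_emg_summary <- function(map, part = region_partition()) {
  stopifnot(inherits(map, "emg_map"), nrow(map) > 0L)
  reg <- classify_region(map$alpha_bin, map$beta_bin, part)
  channels <- unique(map$channel)
  grid <- expand.grid(region = levels(reg), channel = channels,
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- reg == grid$region[i] & map$channel == grid$channel[i]
    n <- sum(map$n[sel])
    data.frame(
      region = grid$region[i], channel = grid$channel[i],
      mean_pct_mvc = if (n > 0) sum(map$mean_pct_mvc[sel] * map$n[sel]) / n else NA_real_,
      n = n
    )
  }))
  most <- vapply(channels, function(ch) {
    sub <- res[res$channel == ch & res$n > 0, ]
    sub$region[which.max(sub$mean_pct_mvc)]
  }, character(1))
  structure(res, most_active = most)
}
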