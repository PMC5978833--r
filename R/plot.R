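# Static workspace figures (azimuth-elevation chart).

#' @importFrom ggplot2 .data
NULL

#' Plot the workspace with its envelope
#'
#' Azimuth–elevation scatter of the pose samples with the reachable-
#' workspace envelope overlaid.
#'
#' @param poses data frame with `alpha`, `beta`.
#' @param envelope optional `envelope_profile` to overlay.
#' @return a ggplot object.
#' @export
plot_workspace <- function(poses, envelope = NULL) {
  p <- ggplot2::ggplot(poses, ggplot2::aes(x = .data$alpha, y = .data$beta)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.3, colour = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(0, 180)) +
    ggplot2::labs(x = "azimuth α (deg)", y = "elevation β (deg)",
                  title = "Reachable workspace") +
    ggplot2::theme_minimal()
  if (!is.null(envelope)) {
    env_df <- data.frame(alpha = envelope$bin_centers, beta = envelope$beta_max)
    p <- p + ggplot2::geom_step(data = env_df[!is.na(env_df$beta), ],
                                colour = "firebrick", linewidth = 0.6)
  }
  p
}

#' Plot an EMG workspace map
#'
#' Colour-tile map of mean %MVC over the azimuth–elevation grid, one facet
#' per channel.
#'
#' @param map an [emg_workspace_map()] result.
#' @return a ggplot object.
#' @export
plot_emg_map <- function(map) {
  stopifnot(inherits(map, "emg_map"))
  cell <- attr(map, "cell")
  ggplot2::ggplot(map, ggplot2::aes(x = .data$alpha_bin, y = .data$beta_bin,
                                    fill = .data$mean_pct_mvc)) +
    ggplot2::geom_tile(width = cell, height = cell) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "%MVC") +
    ggplot2::labs(x = "azimuth α (deg)", y = "elevation β (deg)",
                  title = "Deltoid EMG intensity across the workspace") +
    ggplot2::theme_minimal()
}
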