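#' Intensity-based oligomer analysis of trajectories
#'
#' Normalizes each trajectory's median photon count to a single-fluorophore
#' reference intensity and partitions trajectories into diffusion regimes
#' by their per-trajectory MSD-fitted D, yielding per-regime
#' normalized-intensity distributions (monomers peak at 1, dimers at 2,
#' ...). Only trajectories with more than `min_steps` steps are used.
#'
#' @param trajs Trajectory table (`traj_id`, `frame`, `x_um`, `y_um`,
#'   `photons`).
#' @param reference_intensity Single-fluorophore intensity in photons
#'   (> 0).
#' @param d_bins Breaks (um^2/s) partitioning the diffusion axis, e.g.
#'   `c(0, 0.5, 1.5, Inf)`.
#' @param cfg An [acq_config()].
#' @param min_steps Minimum steps per trajectory (default 10).
#' @return A tibble with class `"oligomer_profile"`: one row per retained
#'   trajectory with `traj_id`, `norm_intensity`, `D_fit`, `d_regime`.
#' @export
oligomer_profile <- function(trajs, reference_intensity,
                             d_bins = c(0, 0.5, 1.5, Inf),
                             cfg = acq_config(), min_steps = 10) {
  if (reference_intensity <= 0) abort("`reference_intensity` must be > 0")
  out <- trajs |>
    group_by(.data$traj_id) |>
    summarise(
      n_steps = dplyr::n() - 1L,
      norm_intensity = median(.data$photons) / reference_intensity,
      D_fit = traj_msd_d(.data$frame, .data$x_um, .data$y_um,
                         cfg$frame_interval, 2, 4),
      .groups = "drop"
    ) |>
    filter(.data$n_steps > min_steps) |>
    mutate(d_regime = cut(.data$D_fit, breaks = d_bins, include.lowest = TRUE))
  structure(out, class = c("oligomer_profile", class(out)),
            reference_intensity = reference_intensity)
}

#' @export
autoplot.oligomer_profile <- function(object, bins = 40, ...) {
  ggplot(object, aes(.data$norm_intensity)) +
    geom_histogram(aes(y = ggplot2::after_stat(density)), bins = bins,
                   fill = "grey75", colour = "grey40") +
    facet_wrap(~d_regime) +
    labs(x = "intensity / single fluorophore", y = "density") +
    theme_minimal()
}
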