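#' Simulate Brownian trajectories in a planar membrane
#'
#' Generates 2D Brownian trajectories from a mixture of diffusive
#' populations plus an optional immobile fraction, observed with Gaussian
#' localization noise. Per coordinate and frame interval the true step is
#' drawn with variance `2 * D * frame_interval`; independent localization
#' noise with the channel precision is added to every observed position, so
#' observed jump variance per coordinate is `2 * (D * dt + sigma_loc^2)`.
#'
#' @param populations A two-column data frame (or tibble) with columns `D`
#'   (diffusion coefficient, um^2/s) and `fraction` (mixture weights of the
#'   mobile particles, summing to 1). A list of `c(D, fraction)` pairs is
#'   also accepted.
#' @param n Total number of particles.
#' @param immobile_fraction Fraction of the `n` particles that are immobile
#'   (D = 0); the mobile remainder is split by `populations$fraction`.
#' @param cfg An [acq_config()].
#' @param channel Channel label (integer, selects the localization
#'   precision).
#'
#' @return A tibble with columns `traj_id`, `frame` (0-based), `x_um`,
#'   `y_um`, `photons`, `background`, `channel`, with the per-particle
#'   ground truth (true D, population, mobility class) attached; retrieve it
#'   with [sim_truth()].
#' @export
#' @examples
#' locs <- sim_planar_trajectories(
#'   data.frame(D = c(2.5, 1.0), fraction = c(0.5, 0.5)),
#'   n = 20, cfg = acq_config(rng_seed = 1)
#' )
#' head(sim_truth(locs))
sim_planar_trajectories <- function(populations,
                                    n,
                                    immobile_fraction = 0,
                                    cfg = acq_config(),
                                    channel = 1L) {
  populations <- normalize_populations(populations)
  if (n < 1) abort("`n` must be >= 1")
  if (immobile_fraction < 0 || immobile_fraction > 1)
    abort("`immobile_fraction` must be in [0, 1]")
  seed_from_config(cfg)

  n_imm <- round(n * immobile_fraction)
  n_mob <- n - n_imm
  # deterministic rounded split across populations, remainder to the largest
  counts <- floor(populations$fraction * n_mob)
  rem <- n_mob - sum(counts)
  if (rem > 0) {
    o <- order(populations$fraction * n_mob - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }

  d_true <- c(rep(populations$D, counts), rep(0, n_imm))
  pop_lab <- c(rep(sprintf("mobile_%d", seq_len(nrow(populations))), counts),
               rep("immobile", n_imm))
  n_tot <- length(d_true)

  fov <- cfg$field_size * cfg$pixel_size
  sig <- channel_precision(cfg, channel)
  nf <- cfg$frame_count
  dt <- cfg$frame_interval

  locs <- purrr::map(seq_len(n_tot), function(i) {
    step_sd <- sqrt(2 * d_true[i] * dt)
    x <- cumsum(c(runif(1, 0, fov), rnorm(nf - 1, 0, step_sd)))
    y <- cumsum(c(runif(1, 0, fov), rnorm(nf - 1, 0, step_sd)))
    tibble(
      traj_id = i,
      frame = seq_len(nf) - 1L,
      x_um = x + rnorm(nf, 0, sig),
      y_um = y + rnorm(nf, 0, sig),
      photons = rpois(nf, cfg$photons_per_fluorophore),
      background = cfg$background_photons,
      channel = as.integer(channel)
    )
  }) |> list_rbind()

  truth <- tibble(
    traj_id = seq_len(n_tot),
    D_true = d_true,
    population = pop_lab,
    mobility_class = ifelse(d_true > 0, "mobile", "immobile")
  )
  with_truth(locs, truth)
}

normalize_populations <- function(populations) {
  if (is.list(populations) && !is.data.frame(populations) &&
      all(vapply(populations, is.numeric, logical(1)))) {
    populations <- do.call(rbind, lapply(populations, function(p) {
      data.frame(D = p[[1]], fraction = p[[2]])
    }))
  }
  populations <- as_tibble(populations)
  if (nrow(populations) == 0) abort("`populations` must contain at least one component")
  if (!all(c("D", "fraction") %in% names(populations)))
    abort("`populations` needs columns `D` and `fraction`")
  if (any(populations$D < 0)) abort("diffusion coefficients must be >= 0")
  if (any(populations$fraction < 0)) abort("fractions must be >= 0")
  if (abs(sum(populations$fraction) - 1) > 1e-8)
    abort("population fractions must sum to 1")
  populations
}

#' Simulate 1D diffusion inside a lipid nanotube
#'
#' The axial coordinate performs 1D Brownian motion with reflecting tube
#' ends; the transverse coordinate is the planar projection of a uniform
#' angular position on a circle of the tube diameter (arcsine-distributed,
#' variance `(diameter/2)^2 / 2`). Localization noise is added to both
#' coordinates.
#'
#' @param D Diffusion coefficient along the tube axis (um^2/s).
#' @param tube_length Tube length in um.
#' @param tube_diameter Tube diameter in um (must be below the pixel size:
#'   the tube is unresolved).
#' @param n Number of particles.
#' @param cfg An [acq_config()].
#' @param channel Channel label.
#' @param origin Tube start `(x, y)` in um; the axis runs along +x.
#'
#' @return Tibble as in [sim_planar_trajectories()]; ground truth carries
#'   the true D, tube length/diameter and the axis. The `y_um` column is the
#'   transverse coordinate about `origin[2]`.
#' @export
sim_nanotube_trajectories <- function(D,
                                      tube_length,
                                      tube_diameter = 0.016,
                                      n = 1,
                                      cfg = acq_config(),
                                      channel = 1L,
                                      origin = c(0, 0)) {
  if (tube_length <= 0) abort("`tube_length` must be > 0")
  if (D < 0) abort("`D` must be >= 0")
  if (tube_diameter >= cfg$pixel_size)
    abort("`tube_diameter` must be below the pixel size (unresolved tube)")
  seed_from_config(cfg)

  sig <- channel_precision(cfg, channel)
  nf <- cfg$frame_count
  dt <- cfg$frame_interval
  step_sd <- sqrt(2 * D * dt)
  r <- tube_diameter / 2

  locs <- purrr::map(seq_len(n), function(i) {
    ax <- cumsum(c(runif(1, 0, tube_length), rnorm(nf - 1, 0, step_sd)))
    ax <- reflect_interval(ax, tube_length)
    trans <- r * cos(runif(nf, 0, 2 * pi))
    tibble(
      traj_id = i,
      frame = seq_len(nf) - 1L,
      x_um = origin[1] + ax + rnorm(nf, 0, sig),
      y_um = origin[2] + trans + rnorm(nf, 0, sig),
      photons = rpois(nf, cfg$photons_per_fluorophore),
      background = cfg$background_photons,
      channel = as.integer(channel)
    )
  }) |> list_rbind()

  truth <- tibble(
    traj_id = seq_len(n),
    D_true = D,
    tube_length = tube_length,
    tube_diameter = tube_diameter,
    axis_x0 = origin[1], axis_y0 = origin[2], axis_angle = 0
  )
  with_truth(locs, truth)
}

# Fold coordinates into [0, L] (reflecting boundaries).
reflect_interval <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}
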