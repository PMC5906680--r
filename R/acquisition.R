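#' Acquisition configuration
#'
#' Bundles the optical and timing parameters shared by the simulator and the
#' analysis stages. All lengths are micrometres, times are seconds, photon
#' quantities are photons per frame. Defaults follow a TIRF setup imaging
#' membrane-bound DNA nanopores: 107 nm pixels, 19 ms frame interval, and
#' localization precisions of 19 nm (far-red channel) and 25 nm (second
#' channel).
#'
#' @param pixel_size Pixel size in um (default 0.107).
#' @param frame_interval Frame interval in s (default 0.019).
#' @param frame_count Number of frames to simulate (default 30).
#' @param field_size Field edge length in pixels (default 64).
#' @param psf_sigma PSF standard deviation in um (default 0.128, i.e. ~1.2 px
#'   for a x150/1.45 NA objective at 670 nm).
#' @param loc_precision Localization precision per channel in um; a named or
#'   unnamed numeric vector, first entry used for channel 1
#'   (default c(0.019, 0.025)).
#' @param photons_per_fluorophore Mean photons emitted per fluorophore per
#'   frame (default 500).
#' @param background_photons Mean background photons per pixel per frame
#'   (default 10).
#' @param rng_seed Integer seed fixing all stochastic output of the
#'   simulators, or NULL to use the current RNG state.
#'
#' @return A list with class `"acq_config"`.
#' @export
#' @examples
#' cfg <- acq_config(frame_count = 50, rng_seed = 1)
#' cfg$pixel_size
acq_config <- function(pixel_size = 0.107,
                       frame_interval = 0.019,
                       frame_count = 30,
                       field_size = 64,
                       psf_sigma = 0.128,
                       loc_precision = c(0.019, 0.025),
                       photons_per_fluorophore = 500,
                       background_photons = 10,
                       rng_seed = NULL) {
  stopifnot(is.numeric(pixel_size), is.numeric(frame_interval))
  if (pixel_size <= 0) abort("`pixel_size` must be > 0")
  if (frame_interval <= 0) abort("`frame_interval` must be > 0")
  if (frame_count < 1) abort("`frame_count` must be >= 1")
  if (field_size < 1) abort("`field_size` must be >= 1")
  if (psf_sigma <= 0) abort("`psf_sigma` must be > 0")
  if (any(loc_precision < 0)) abort("`loc_precision` must be >= 0")
  if (photons_per_fluorophore <= 0) abort("`photons_per_fluorophore` must be > 0")
  if (background_photons < 0) abort("`background_photons` must be >= 0")
  if (!is.null(rng_seed)) rng_seed <- as.integer(rng_seed)
  structure(
    list(
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      frame_count = as.integer(frame_count),
      field_size = as.integer(field_size),
      psf_sigma = psf_sigma,
      loc_precision = loc_precision,
      photons_per_fluorophore = photons_per_fluorophore,
      background_photons = background_photons,
      rng_seed = rng_seed
    ),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat("<acq_config>\n")
  cat(sprintf("  pixel size      : %g um (%g nm)\n", x$pixel_size, x$pixel_size * 1e3))
  cat(sprintf("  frame interval  : %g s\n", x$frame_interval))
  cat(sprintf("  frames / field  : %d / %d px\n", x$frame_count, x$field_size))
  cat(sprintf("  psf sigma       : %g um\n", x$psf_sigma))
  cat(sprintf("  loc precision   : %s um\n", paste(x$loc_precision, collapse = ", ")))
  cat(sprintf("  photons/fluor   : %g; background %g /px/frame\n",
              x$photons_per_fluorophore, x$background_photons))
  cat(sprintf("  rng seed        : %s\n", x$rng_seed %||% "<unset>"))
  invisible(x)
}

# Seed the RNG from the config without touching callers that manage the RNG
# themselves (rng_seed = NULL).
seed_from_config <- function(cfg) {
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  invisible(NULL)
}

# channel -> localization precision (um)
channel_precision <- function(cfg, channel) {
  p <- cfg$loc_precision
  idx <- pmin(as.integer(channel), length(p))
  unname(p[idx])
}

#' Ground truth attached to simulated data
#'
#' Every simulator records the generating parameters of each particle, trace,
#' pattern or curve in a tibble attached to its output. `sim_truth()`
#' retrieves it.
#'
#' @param x An object returned by one of the `sim_*()` generators.
#' @return A tibble of ground-truth records (one row per simulated entity).
#' @export
sim_truth <- function(x) {
  tr <- attr(x, "truth", exact = TRUE)
  if (is.null(tr)) abort("no ground truth attached to this object")
  tr
}

with_truth <- function(x, truth) {
  attr(x, "truth") <- truth
  x
}
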