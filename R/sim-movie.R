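#' Render a localization table into a synthetic image stack
#'
#' Draws every localization as an integrated 2D Gaussian PSF (the Gaussian
#' integrated over each pixel via `pnorm` differences) of width
#' `cfg$psf_sigma`, scaled so the spot integral equals the localization's
#' `photons`, on a constant background, then applies Poisson shot noise.
#' Intended to exercise the localization stage against known emitter
#' positions.
#'
#' @param locs Tibble with `frame`, `x_um`, `y_um` and optionally `photons`
#'   (defaults to `cfg$photons_per_fluorophore`).
#' @param cfg An [acq_config()]; `field_size` and `pixel_size` define the
#'   raster, `background_photons` the constant background.
#' @param shot_noise Apply Poisson noise (default TRUE). With FALSE the
#'   noiseless expected image is returned.
#' @param n_frames Number of frames; defaults to `max(locs$frame) + 1`.
#'
#' @return A numeric array `c(ny, nx, n_frames)` of photon counts with class
#'   `"image_stack"`, pixel (1,1) covering `[0, pixel) x [0, pixel)` um.
#' @export
sim_movie <- function(locs, cfg = acq_config(), shot_noise = TRUE,
                      n_frames = NULL) {
  npx <- cfg$field_size
  px <- cfg$pixel_size
  fov <- npx * px
  if (is.null(n_frames)) n_frames <- max(locs$frame) + 1L
  if (!"photons" %in% names(locs)) locs$photons <- cfg$photons_per_fluorophore

  out_of_field <- locs$x_um < 0 | locs$x_um > fov | locs$y_um < 0 | locs$y_um > fov
  if (any(out_of_field)) {
    warn(sprintf("%d localizations outside the field were clipped", sum(out_of_field)))
    locs$x_um <- pmin(pmax(locs$x_um, 0), fov)
    locs$y_um <- pmin(pmax(locs$y_um, 0), fov)
  }

  edges <- seq(0, fov, by = px)
  stack <- array(cfg$background_photons, dim = c(npx, npx, n_frames))
  s <- cfg$psf_sigma
  for (k in seq_len(nrow(locs))) {
    f <- locs$frame[k] + 1L
    if (f < 1 || f > n_frames) next
    # integrated Gaussian: photon mass per pixel row/column
    wx <- diff(pnorm(edges, locs$x_um[k], s))
    wy <- diff(pnorm(edges, locs$y_um[k], s))
    stack[, , f] <- stack[, , f] + locs$photons[k] * outer(wy, wx)
  }
  if (shot_noise) {
    seed_from_config(cfg)
    stack[] <- rpois(length(stack), stack)
  }
  structure(stack, class = "image_stack", pixel_size = px)
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' @param stack Numeric array `c(ny, nx, n_frames)` of photon counts.
#' @param path Output file.
#' @param scale Divisor mapping photons to the 16-bit range; counts are
#'   clipped at 65535 after scaling.
#' @return `path`, invisibly (write) or an `"image_stack"` array (read).
#' @export
write_stack_tiff <- function(stack, path, scale = 1) {
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- pmin(pmax(stack[, , f] / scale, 0), 65535)
    m / 65535  # tiff package expects [0,1]; 16-bit written below
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]] * 65535 * scale
  structure(stack, class = "image_stack")
}
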