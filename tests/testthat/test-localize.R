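px <- 0.107

test_that("noiseless symmetric spot is fitted without bias", {
  cfg <- acq_config(field_size = 16, frame_count = 1, rng_seed = 1)
  truth <- tibble::tibble(frame = 0L, x_um = 8 * px, y_um = 8 * px,
                          photons = 2000)
  stack <- sim_movie(truth, cfg, shot_noise = FALSE)
  det <- locate_emitters(stack, cfg)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_um - truth$x_um) / px, 1e-3)
  expect_lt(abs(det$y_um - truth$y_um) / px, 1e-3)
  expect_lt(abs(det$photons - 2000) / 2000, 0.01)
  expect_lt(abs(det$background - cfg$background_photons), 0.5)
})

test_that("two emitters five pixels apart give two rows; empty frames none", {
  cfg <- acq_config(field_size = 20, frame_count = 2, rng_seed = 2)
  truth <- tibble::tibble(frame = 0L, x_um = c(7, 12) * px, y_um = 10 * px,
                          photons = 1500)
  stack <- sim_movie(truth, cfg, shot_noise = FALSE, n_frames = 2)
  det <- locate_emitters(stack, cfg)
  expect_equal(sum(det$frame == 0), 2)
  expect_equal(sum(det$frame == 1), 0)  # background-only frame, zero rows
})

test_that("localization spread tracks photon count (tuned ~19 nm case and 1/sqrt(N) law)", {
  # at 250 photons/frame on an 18.5-photon background the empirical spread
  # matches the 19 nm single-channel precision
  cfg <- acq_config(field_size = 16, frame_count = 250,
                    photons_per_fluorophore = 250,
                    background_photons = 18.5, rng_seed = 3)
  truth <- tibble::tibble(frame = 0:249, x_um = 8.3 * px, y_um = 7.7 * px,
                          photons = 250)
  det <- locate_emitters(sim_movie(truth, cfg, shot_noise = TRUE), cfg)
  near <- det[abs(det$x_um - 8.3 * px) < 2 * px &
                abs(det$y_um - 7.7 * px) < 2 * px, ]
  expect_gt(nrow(near), 200)
  spread_nm <- sd(c(near$x_um - mean(near$x_um),
                    near$y_um - mean(near$y_um))) * 1000
  expect_gt(spread_nm, 12)
  expect_lt(spread_nm, 27)

  # power law: spread ~ N^-1/2 over a 10x photon range (no background)
  spreads <- vapply(c(100, 300, 1000), function(nph) {
    cfgN <- acq_config(field_size = 16, frame_count = 120,
                       photons_per_fluorophore = nph,
                       background_photons = 2, rng_seed = 300 + nph)
    tt <- tibble::tibble(frame = 0:119, x_um = 8.3 * px, y_um = 7.7 * px,
                         photons = nph)
    dd <- locate_emitters(sim_movie(tt, cfgN, shot_noise = TRUE), cfgN)
    dd <- dd[abs(dd$x_um - 8.3 * px) < 2 * px & abs(dd$y_um - 7.7 * px) < 2 * px, ]
    sd(c(dd$x_um - mean(dd$x_um), dd$y_um - mean(dd$y_um)))
  }, double(1))
  slope <- coef(lm(log(spreads) ~ log(c(100, 300, 1000))))[2]
  expect_lt(abs(unname(slope) + 0.5), 0.1)
})

test_that("median image suppresses outliers and mobile emitters", {
  cfg <- acq_config(field_size = 20, frame_count = 5, rng_seed = 4)
  # constant stack: median identical
  still <- tibble::tibble(frame = 0:4, x_um = 5 * px, y_um = 5 * px, photons = 1000)
  st <- sim_movie(still, cfg, shot_noise = FALSE)
  expect_equal(median_image(st, 5), st[, , 1], ignore_attr = TRUE)
  # an outlier frame is suppressed entirely
  out <- dplyr::bind_rows(still,
                          tibble::tibble(frame = 2L, x_um = 15 * px,
                                         y_um = 15 * px, photons = 5000))
  st2 <- sim_movie(out, cfg, shot_noise = FALSE)
  mi <- median_image(st2, 5)
  expect_equal(mi, st[, , 1], ignore_attr = TRUE)
  # a crossing mobile emitter is attenuated relative to an immobile one
  mob <- tibble::tibble(frame = 0:4, x_um = (3 + 3 * (0:4)) * px,
                        y_um = 15 * px, photons = 1000)
  st3 <- sim_movie(dplyr::bind_rows(still, mob), cfg, shot_noise = FALSE)
  mi3 <- median_image(st3, 5)
  immobile_peak <- max(mi3[1:10, 1:10])
  mobile_peak <- max(mi3[11:20, ])
  expect_gt(immobile_peak, 3 * mobile_peak)
  expect_error(median_image(st3, 0), ">= 1")
  expect_error(median_image(st3, 99), "exceeds")
})

test_that("extracted traces follow the emitter level", {
  cfg <- acq_config(field_size = 16, frame_count = 40, rng_seed = 5)
  two_level <- dplyr::bind_rows(
    tibble::tibble(frame = 0:19, x_um = 8 * px, y_um = 8 * px, photons = 1000),
    tibble::tibble(frame = 20:39, x_um = 8 * px, y_um = 8 * px, photons = 0)
  )
  st <- sim_movie(two_level, cfg, shot_noise = FALSE)
  tr <- extract_trace(st, c(8 * px, 8 * px), radius_px = 4, cfg = cfg)
  expect_equal(nrow(tr), 40)
  expect_lt(abs(mean(tr$photons[1:20]) - 1000) / 1000, 0.05)
  expect_lt(abs(mean(tr$photons[21:40])), 20)   # post-bleach ~ 0
  expect_false(attr(tr, "partial_aperture"))
  expect_warning(extract_trace(st, c(0.05, 0.05), radius_px = 4, cfg = cfg),
                 "partial")
  expect_error(extract_trace(st, c(-1, 0.5), cfg = cfg), "outside")
})

test_that("TALM histogram conserves localization count", {
  cfg <- acq_config(frame_count = 50, rng_seed = 6)
  locs <- sim_planar_trajectories(data.frame(D = 0.5, fraction = 1), n = 30,
                                  cfg = cfg)
  img <- render_talm(locs, bin_nm = 20)
  expect_equal(sum(img), nrow(locs))
  one <- render_talm(locs[1, ], bin_nm = 20)
  expect_equal(sum(one > 0), 1)
  expect_equal(sum(one), 1)
  expect_error(render_talm(locs, bin_nm = 0), "> 0")
  expect_error(render_talm(locs[0, ], bin_nm = 10), "empty")
})

test_that("transverse FWHM recovers 2.3548 sigma and the tube closed form", {
  set.seed(7)
  gauss <- tibble::tibble(x_um = runif(3000, 0, 10),
                          y_um = rnorm(3000, 2, 0.019))
  fw <- profile_fwhm(gauss, axis_line = c(0, 2, 0))
  expect_lt(abs(fw$fwhm_nm - 2.3548 * 19) / (2.3548 * 19), 0.06)
  # tube: diameter 16 nm + 19 nm precision -> FWHM = 2.3548*sqrt(19^2 + 32)
  cfg <- acq_config(frame_count = 900, rng_seed = 8)
  tube <- sim_nanotube_trajectories(1.0, 20, 0.016, n = 2, cfg = cfg,
                                    origin = c(0, 5))
  fw2 <- profile_fwhm(tube, axis_line = c(0, 5, 0))
  expected <- 2.3548 * sqrt(19^2 + (16 / (2 * sqrt(2)))^2)
  expect_lt(abs(fw2$fwhm_nm - expected) / expected, 0.08)
  expect_true(fw2$converged)
  # rendered-image profile agrees with the raw-localization profile
  img <- render_talm(tube, bin_nm = 5)
  fw3 <- profile_fwhm(img, axis_line = c(0, 5, 0))
  expect_lt(abs(fw3$fwhm_nm - fw2$fwhm_nm) / fw2$fwhm_nm, 0.15)
  expect_error(profile_fwhm(gauss[1:10, ], axis_line = c(0, 2, 0)), ">= 50")
  # deconvolution model
  dec <- deconvolve_width(fw2$fwhm_nm, 19)
  expect_lt(abs(dec$diameter_nm - 16), 4)
})

test_that("image stacks round-trip through 16-bit TIFF", {
  cfg <- acq_config(field_size = 12, frame_count = 3, rng_seed = 9)
  st <- sim_movie(tibble::tibble(frame = 0:2, x_um = 0.6, y_um = 0.6,
                                 photons = 800), cfg)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(st, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back), dim(st))
  expect_equal(round(back), round(unclass(st)), ignore_attr = TRUE)
})
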