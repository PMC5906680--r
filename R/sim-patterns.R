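#' Simulate a partially correlated point-pattern pair
#'
#' Emulates immobile cluster positions localized in the same membrane area
#' at two time points (e.g. before and after photobleaching): pattern B
#' retains a fraction `alpha_true` of pattern A's points, each displaced by
#' isotropic Gaussian jitter with per-coordinate s.d. `displacement_sigma`;
#' the remaining points of B are redistributed uniformly so both patterns
#' have equal density.
#'
#' @param density Point density in um^-2.
#' @param alpha_true Correlated (persisting) fraction in `[0, 1]`.
#' @param displacement_sigma Per-coordinate jitter s.d. in um; the pair
#'   distance of a persisting point is then Rayleigh with scale
#'   `displacement_sigma`, so the PICCS correlation length equals it.
#' @param area Field area in um^2 (square field).
#' @param cfg An [acq_config()] (only the seed is used).
#'
#' @return Tibble with columns `pattern` ("A"/"B"), `x_um`, `y_um`; ground
#'   truth via [sim_truth()].
#' @export
#' @examples
#' pp <- sim_point_pattern_pair(2, 0.092, 0.0225, area = 100,
#'                              cfg = acq_config(rng_seed = 3))
#' table(pp$pattern)
sim_point_pattern_pair <- function(density,
                                   alpha_true,
                                   displacement_sigma,
                                   area,
                                   cfg = acq_config()) {
  if (alpha_true < 0 || alpha_true > 1) abort("`alpha_true` must be in [0, 1]")
  if (density <= 0 || area <= 0) abort("`density` and `area` must be > 0")
  if (density * area < 10)
    warn("fewer than 10 expected points: spatial correlation will be unstable")
  seed_from_config(cfg)

  side <- sqrt(area)
  n <- round(density * area)
  a <- tibble(pattern = "A", x_um = runif(n, 0, side), y_um = runif(n, 0, side))
  n_keep <- round(alpha_true * n)
  keep <- sample.int(n, n_keep)
  b_kept <- tibble(
    pattern = "B",
    x_um = a$x_um[keep] + rnorm(n_keep, 0, displacement_sigma),
    y_um = a$y_um[keep] + rnorm(n_keep, 0, displacement_sigma)
  )
  b_new <- tibble(pattern = "B",
                  x_um = runif(n - n_keep, 0, side),
                  y_um = runif(n - n_keep, 0, side))
  out <- bind_rows(a, b_kept, b_new)
  with_truth(out, tibble(
    alpha_true = alpha_true,
    displacement_sigma = displacement_sigma,
    density = density,
    side = side,
    n_points = n,
    n_correlated = n_keep
  ))
}
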