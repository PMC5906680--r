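#' Simulate a pseudo-first-order surface-binding curve
#'
#' Association phase: `R(t) = Req * (1 - exp(-(ka*C + kd) * t))` with
#' `Req = rmax * ka * C / (ka * C + kd)`. Dissociation phase (buffer wash):
#' `R(t) = R(t_assoc) * exp(-kd * (t - t_assoc))`. Additive Gaussian noise.
#'
#' @param ka Association rate constant (M^-1 s^-1), >= 0.
#' @param kd Dissociation rate constant (s^-1), >= 0.
#' @param conc Analyte concentration (M), >= 0.
#' @param t_assoc,t_diss Phase durations in s.
#' @param noise_sigma Additive Gaussian noise s.d. (signal units).
#' @param cfg An [acq_config()] (seed only).
#' @param rmax Saturation signal (default 1).
#' @param t_step Sampling interval in s (default 1).
#'
#' @return Tibble `t_s`, `signal`, `phase`, with analyte concentration and
#'   true rates attached as ground truth.
#' @export
#' @examples
#' bc <- sim_binding_curve(1.5e5, 4.1e-4, 1e-7, 220, 220, 0)
#' sim_truth(bc)$k_obs  # 1.5e5 * 1e-7 + 4.1e-4 = 0.01541
sim_binding_curve <- function(ka, kd, conc,
                              t_assoc = 220, t_diss = 220,
                              noise_sigma = 0,
                              cfg = acq_config(),
                              rmax = 1,
                              t_step = 1) {
  if (ka < 0 || kd < 0) abort("rate constants must be >= 0")
  if (conc < 0) abort("`conc` must be >= 0")
  seed_from_config(cfg)

  k_obs <- ka * conc + kd
  req <- if (k_obs > 0) rmax * ka * conc / k_obs else 0
  t_a <- seq(0, t_assoc, by = t_step)
  t_d <- seq(t_assoc + t_step, t_assoc + t_diss, by = t_step)
  r_end <- req * (1 - exp(-k_obs * t_assoc))
  curve <- bind_rows(
    tibble(t_s = t_a, signal = req * (1 - exp(-k_obs * t_a)), phase = "association"),
    tibble(t_s = t_d, signal = r_end * exp(-kd * (t_d - t_assoc)), phase = "dissociation")
  )
  curve$signal <- curve$signal + rnorm(nrow(curve), 0, noise_sigma)
  attr(curve, "conc") <- conc
  with_truth(curve, tibble(ka = ka, kd = kd, conc = conc,
                           k_obs = k_obs, req = req, rmax = rmax))
}
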