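#' Fit pseudo-first-order binding kinetics phase by phase
#'
#' Fits the two phases of a surface-binding curve separately, in the order
#' the information flows: the dissociation phase first with
#' `R(t) = R0 * exp(-kd * (t - t0))`, then the association phase with
#' `R(t) = Req * (1 - exp(-k_obs * t))`. The association rate constant
#' follows as `ka = (k_obs - kd) / C` and the equilibrium dissociation
#' constant as `KD = kd / ka`. A global simultaneous fit of both phases is
#' available with `global = TRUE`.
#'
#' @param curve Tibble with `t_s`, `signal`, `phase`
#'   ("association"/"dissociation"), e.g. from [sim_binding_curve()]; each
#'   phase needs >= 10 points.
#' @param conc Analyte concentration in M; defaults to the `conc`
#'   attribute of `curve`.
#' @param global Fit both phases simultaneously instead of sequentially
#'   (default FALSE).
#'
#' @return A `"kinetic_fit"`: list with `ka` (M^-1 s^-1), `kd` (s^-1),
#'   `k_obs` (s^-1), `req`, `KD` (M), `conc`, residual norms per phase and
#'   a `flags` character vector (`"ka_nonidentifiable"` when
#'   `k_obs <= kd`).
#' @export
#' @examples
#' bc <- sim_binding_curve(1.5e5, 4.1e-4, 1e-7, noise_sigma = 0)
#' fit <- fit_binding_phases(bc)
#' c(fit$ka, fit$kd)
fit_binding_phases <- function(curve, conc = NULL, global = FALSE) {
  conc <- conc %||% attr(curve, "conc")
  if (is.null(conc)) abort("supply `conc` (analyte concentration in M)")
  assoc <- curve[curve$phase == "association", ]
  diss <- curve[curve$phase == "dissociation", ]
  if (nrow(assoc) < 10 || nrow(diss) < 10)
    abort("each phase needs at least 10 points")
  t0 <- min(diss$t_s)
  flags <- character(0)

  # dissociation: R0 * exp(-kd * (t - t0)); log-linear start
  d0 <- diss$signal[which.min(diss$t_s)]
  kd0 <- {
    pos <- diss$signal > 0
    if (sum(pos) > 2) {
      sl <- -unname(coef(lm(log(diss$signal[pos]) ~ diss$t_s[pos]))[2])
      max(sl, 1e-8)
    } else 1e-4
  }
  resid_diss <- 0
  if (sd(diss$signal) < 1e-12 * max(abs(diss$signal), 1)) {
    # flat dissociation: no measurable decay
    kd <- 0
    if (max(abs(diss$signal)) < 1e-12) flags <- c(flags, "empty_dissociation")
  } else {
    dfit <- nls(signal ~ r0 * exp(-kd * (t_s - t0)), data = diss,
                start = list(r0 = max(d0, 1e-8), kd = kd0),
                control = stats::nls.control(maxiter = 1000, warnOnly = TRUE,
                                             scaleOffset = 1, tol = 1e-10,
                                             minFactor = 1e-10))
    kd <- max(unname(coef(dfit)["kd"]), 0)
    resid_diss <- sqrt(mean(stats::residuals(dfit)^2))
  }

  if (global) {
    obj <- function(p) {
      req <- p[1]; kobs <- exp(p[2]); kdg <- exp(p[3])
      ra <- req * (1 - exp(-kobs * assoc$t_s))
      r_end <- req * (1 - exp(-kobs * t0))
      rd <- r_end * exp(-kdg * (diss$t_s - t0))
      sum((ra - assoc$signal)^2) + sum((rd - diss$signal)^2)
    }
    p0 <- c(max(assoc$signal), log(max(conc * 1e5 + kd, 1e-6)), log(max(kd, 1e-8)))
    gfit <- optim(p0, obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-14))
    req <- gfit$par[1]; k_obs <- exp(gfit$par[2]); kd <- exp(gfit$par[3])
    resid_assoc <- sqrt(obj(gfit$par) / (nrow(assoc) + nrow(diss)))
    resid_diss <- resid_assoc
  } else if (sd(assoc$signal) < 1e-12 * max(abs(assoc$signal), 1)) {
    # flat association: no binding signal, k_obs pinned to kd
    req <- 0
    k_obs <- kd
    resid_assoc <- 0
    flags <- c(flags, "empty_association")
  } else {
    # association with kd fixed from the dissociation fit
    a_max <- max(assoc$signal)
    k0 <- max(conc * 1e5 + kd, 1e-6)
    afit <- nls(signal ~ req * (1 - exp(-kobs * t_s)), data = assoc,
                start = list(req = a_max, kobs = k0),
                control = stats::nls.control(maxiter = 1000, warnOnly = TRUE,
                                             scaleOffset = 1, tol = 1e-10,
                                             minFactor = 1e-10))
    req <- unname(coef(afit)["req"])
    k_obs <- unname(coef(afit)["kobs"])
    resid_assoc <- sqrt(mean(stats::residuals(afit)^2))
  }

  if (k_obs <= kd) {
    flags <- c(flags, "ka_nonidentifiable")
    ka <- NA_real_
  } else {
    ka <- (k_obs - kd) / conc
  }
  structure(list(
    ka = ka, kd = kd, k_obs = k_obs, req = req,
    KD = if (is.finite(ka) && ka > 0) kd / ka else NA_real_,
    conc = conc, resid_assoc = resid_assoc, resid_diss = resid_diss,
    flags = flags, global = global
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit>", if (x$global) "(global)" else "(sequential)", "\n")
  cat(sprintf("  ka    = %.4g M^-1 s^-1\n", x$ka))
  cat(sprintf("  kd    = %.4g s^-1\n", x$kd))
  cat(sprintf("  k_obs = %.4g s^-1  (C = %.3g M)\n", x$k_obs, x$conc))
  cat(sprintf("  KD    = %.4g M, Req = %.4g\n", x$KD, x$req))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(term = c("ka", "kd", "k_obs", "Req", "KD"),
         estimate = c(x$ka, x$kd, x$k_obs, x$req, x$KD),
         unit = c("M^-1 s^-1", "s^-1", "s^-1", "signal", "M"))
}

#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(ka = x$ka, kd = x$kd, k_obs = x$k_obs, KD = x$KD, req = x$req,
         resid_assoc = x$resid_assoc, resid_diss = x$resid_diss,
         flags = paste(x$flags, collapse = ";"))
}

#' @export
autoplot.kinetic_fit <- function(object, curve = NULL, ...) {
  if (is.null(curve)) abort("pass the fitted `curve` to plot")
  t0 <- min(curve$t_s[curve$phase == "dissociation"])
  r_end <- object$req * (1 - exp(-object$k_obs * t0))
  curve$fitted <- ifelse(
    curve$phase == "association",
    object$req * (1 - exp(-object$k_obs * curve$t_s)),
    r_end * exp(-object$kd * (curve$t_s - t0))
  )
  ggplot(curve, aes(.data$t_s, .data$signal)) +
    geom_point(size = 0.5, alpha = 0.5) +
    geom_line(aes(y = .data$fitted), colour = "red") +
    labs(x = "time (s)", y = "signal") + theme_minimal()
}

#' Convert a surface mass signal to a molecular surface density
#'
#' `density = mass_signal * N_A / molar_mass`, unit-converted from
#' ng mm^-2 to molecules um^-2; the side of the square area available per
#' molecule is `sqrt(1/density)`.
#'
#' @param mass_signal Surface mass density in ng mm^-2 (> 0).
#' @param molar_mass Molar mass in g mol^-1 (> 0).
#' @return One-row tibble: `density_um2` (molecules per um^2),
#'   `area_side_nm` (nm).
#' @export
#' @examples
#' surface_density(0.8, 96000)  # ~5000 um^-2, ~14 nm
surface_density <- function(mass_signal, molar_mass) {
  if (mass_signal <= 0 || molar_mass <= 0)
    abort("`mass_signal` and `molar_mass` must be > 0")
  na <- 6.02214076e23
  # 1 ng mm^-2 = 1e-9 g / 1e6 um^2 = 1e-15 g um^-2
  dens <- mass_signal * 1e-15 * na / molar_mass
  tibble(density_um2 = dens, area_side_nm = sqrt(1e6 / dens))
}

#' Molar mass of an oligonucleotide assembly from strand compositions
#'
#' Sums per-strand molar masses from base counts using linear DNA
#' monophosphate residue masses (A 313.21, C 289.18, G 329.21, T 304.20
#' g/mol) plus 79.0 g/mol per strand for the terminal 5'-phosphate/OH
#' correction (61.96 subtracted for the condensation convention used:
#' each strand mass = sum(residues) - 61.96).
#'
#' @param strands Data frame with columns `n_a`, `n_c`, `n_g`, `n_t`
#'   (counts per strand), one row per strand; or a path to such a CSV.
#' @return Total molar mass in g/mol.
#' @export
oligo_molar_mass <- function(strands) {
  if (is.character(strands)) strands <- utils::read.csv(strands)
  req <- c("n_a", "n_c", "n_g", "n_t")
  if (!all(req %in% names(strands))) abort("need columns n_a, n_c, n_g, n_t")
  masses <- c(a = 313.21, c = 289.18, g = 329.21, t = 304.20)
  per_strand <- strands$n_a * masses["a"] + strands$n_c * masses["c"] +
    strands$n_g * masses["g"] + strands$n_t * masses["t"] - 61.96
  sum(per_strand)
}
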