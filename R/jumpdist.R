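#' Jump-magnitude probability densities
#'
#' Density of observed jump magnitudes at one lag for free Brownian motion
#' observed with localization noise. With the per-dimension mean square
#' displacement `v = MSD(t) = 2*(D*t + eps^2)`, the magnitude is
#' half-normal in 1D, `P(x) = sqrt(2/(pi*v)) * exp(-x^2/(2v))`, and
#' Rayleigh in 2D, `P(x) = x/v * exp(-x^2/(2v))`. Mixtures are weighted
#' sums of these with component scales `v_i`.
#'
#' @param x Jump magnitudes (um, >= 0).
#' @param v Per-dimension MSD scale(s) `2*(D*t + eps^2)` (um^2).
#' @param w Mixture weights (default equal mass on a single component).
#' @param d Dimensionality (1 or 2).
#' @return Densities.
#' @export
djump <- function(x, v, w = rep(1 / length(v), length(v)), d = 2) {
  stopifnot(length(v) == length(w), d %in% c(1, 2))
  out <- numeric(length(x))
  for (k in seq_along(v)) {
    out <- out + w[k] * if (d == 2) {
      x / v[k] * exp(-x^2 / (2 * v[k]))
    } else {
      sqrt(2 / (pi * v[k])) * exp(-x^2 / (2 * v[k]))
    }
  }
  out
}

#' Fit a jump-distance mixture model
#'
#' Maximum-likelihood fit of a half-normal (1D) or Rayleigh (2D) mixture to
#' jump magnitudes at a fixed lag, by expectation-maximization with
#' multiple starts. Each component has per-dimension scale
#' `v_i = 2*(D_i*dt + eps^2)`; a single optical precision `eps` is shared
#' by all components and must be supplied (it is not identifiable from a
#' single lag). When `n_components` is a vector, the model is selected by
#' BIC.
#'
#' A histogram least-squares variant (`method = "histogram"`) is available
#' for parity with binned step-length fitting; MLE is the default for its
#' bin-free small-sample behaviour.
#'
#' @param jumps Jump magnitudes (um) at one lag, e.g. from
#'   [jump_magnitudes()].
#' @param d Dimensionality (1 or 2).
#' @param n_components Number of mixture components, or a vector of
#'   candidates for BIC selection (values in 1:3 typical).
#' @param dt Lag time in seconds.
#' @param eps Localization precision in um (default 0.019).
#' @param method `"mle"` (EM) or `"histogram"`.
#' @param n_starts Random restarts for EM (default 5).
#' @param bins Histogram bin count for `method = "histogram"` (default 60).
#'
#' @return A `"jump_fit"` object: list with `components` (tibble `D_um2_s`,
#'   `weight`, `v_um2`, sorted by descending D), `eps_um`, `dt_s`, `d`,
#'   `loglik`, `bic`, `n`, `n_components`, `method`, `converged`.
#' @export
#' @examples
#' set.seed(1)
#' r <- sqrt(rexp(2000, 1 / 0.08))  # Rayleigh, v = 0.04
#' fit <- fit_jump_distribution(r, d = 2, n_components = 1, dt = 0.019)
#' fit$components$D_um2_s
fit_jump_distribution <- function(jumps, d = 2, n_components = 1,
                                  dt, eps = 0.019,
                                  method = c("mle", "histogram"),
                                  n_starts = 5, bins = 60) {
  method <- match.arg(method)
  stopifnot(d %in% c(1, 2), all(n_components >= 1))
  jumps <- jumps[is.finite(jumps) & jumps > 0]
  if (length(jumps) < 10) abort("need at least 10 positive jump magnitudes")

  fits <- purrr::map(n_components, function(k) {
    if (method == "mle") {
      fit_mix_em(jumps, k, d, n_starts)
    } else {
      fit_mix_hist(jumps, k, d, bins)
    }
  })
  bics <- purrr::map_dbl(fits, "bic")
  best <- fits[[which.min(bics)]]

  comp <- tibble(
    v_um2 = best$v,
    weight = best$w,
    D_um2_s = pmax((best$v / 2 - eps^2) / dt, 0)
  ) |> arrange(dplyr::desc(.data$D_um2_s))

  structure(list(
    components = comp, eps_um = eps, dt_s = dt, d = d,
    loglik = best$loglik, bic = best$bic, n = length(jumps),
    n_components = length(best$v), method = method,
    converged = best$converged,
    bic_path = setNames(bics, n_components),
    jumps = jumps
  ), class = "jump_fit")
}

# EM for a mixture of Rayleigh (d=2) / half-normal (d=1) scales.
fit_mix_em <- function(x, k, d, n_starts, max_iter = 500, tol = 1e-9) {
  n <- length(x)
  x2 <- x^2
  # scale MLE given responsibilities:
  #   Rayleigh: v = sum(g*x^2)/(2*sum(g)); half-normal: v = sum(g*x^2)/sum(g)
  denom <- if (d == 2) 2 else 1
  one_run <- function(v0, w0) {
    v <- v0; w <- w0
    ll_old <- -Inf
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j) djump(x, v[j], 1, d), double(n))
      dens <- sweep(as.matrix(dens), 2, w, `*`)
      tot <- rowSums(dens)
      tot[tot <= 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      g <- dens / tot
      w <- colMeans(g)
      v <- colSums(g * x2) / (denom * colSums(g))
      v <- pmax(v, 1e-12)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
        conv <- TRUE; ll_old <- ll; break
      }
      ll_old <- ll
    }
    list(v = v, w = w, loglik = ll_old, converged = conv)
  }
  # quantile-based start + random restarts
  v0 <- if (k == 1) {
    mean(x2) / denom
  } else {
    vapply(split(sort(x2), cut(seq_along(x2), k, labels = FALSE)),
           mean, double(1)) / denom
  }
  starts <- list(list(v = v0, w = rep(1 / k, k)))
  if (k > 1 && n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      f <- runif(k, 0.3, 3)
      starts <- c(starts, list(list(v = mean(x2) / denom * f,
                                    w = as.vector(prop_table(runif(k, 0.5, 1.5))))))
    }
  }
  runs <- purrr::map(starts, function(s) one_run(s$v, s$w))
  best <- runs[[which.max(purrr::map_dbl(runs, "loglik"))]]
  p <- 2 * k - 1
  best$bic <- -2 * best$loglik + p * log(n)
  best
}

prop_table <- function(x) x / sum(x)

# least-squares fit of the mixture pdf to a density-normalized histogram
fit_mix_hist <- function(x, k, d, bins) {
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  mids <- h$mids; dens <- h$density
  obj <- function(p) {
    v <- exp(p[seq_len(k)])
    w <- if (k > 1) prop_table(exp(c(p[(k + 1):(2 * k - 1)], 0))) else 1
    sum((djump(mids, v, w, d) - dens)^2)
  }
  p0 <- c(log(mean(x^2) / ifelse(d == 2, 2, 1) * seq(0.5, 2, length.out = k)),
          rep(0, k - 1))
  fit <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  v <- exp(fit$par[seq_len(k)])
  w <- if (k > 1) prop_table(exp(c(fit$par[(k + 1):(2 * k - 1)], 0))) else 1
  ll <- sum(log(pmax(djump(x, v, w, d), .Machine$double.xmin)))
  list(v = v, w = w, loglik = ll, bic = -2 * ll + (2 * k - 1) * log(length(x)),
       converged = fit$convergence == 0)
}

#' @export
print.jump_fit <- function(x, ...) {
  cat(sprintf("<jump_fit> %dD %s, %d component(s), n = %d jumps\n",
              x$d, x$method, x$n_components, x$n))
  print(as.data.frame(x$components), row.names = FALSE)
  cat(sprintf("  eps = %g um, dt = %g s, logLik = %.2f, BIC = %.2f\n",
              x$eps_um, x$dt_s, x$loglik, x$bic))
  invisible(x)
}

#' @export
tidy.jump_fit <- function(x, ...) {
  mutate(x$components, component = row_number(), .before = 1)
}

#' @export
glance.jump_fit <- function(x, ...) {
  tibble(n_components = x$n_components, logLik = x$loglik, BIC = x$bic,
         n = x$n, d = x$d, method = x$method, converged = x$converged)
}

#' @export
autoplot.jump_fit <- function(object, bins = 60, ...) {
  df <- tibble(jump = object$jumps)
  grid <- tibble(x = seq(0, max(df$jump), length.out = 400))
  grid$density <- djump(grid$x, object$components$v_um2,
                        object$components$weight, object$d)
  ggplot(df, aes(.data$jump)) +
    geom_histogram(aes(y = ggplot2::after_stat(density)), bins = bins,
                   fill = "grey80", colour = "grey50") +
    geom_line(data = grid, aes(.data$x, .data$density), colour = "red") +
    labs(x = "jump magnitude (µm)", y = "probability density") +
    theme_minimal()
}
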