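#' Pooled mean square displacement curve
#'
#' Computes MSD(lag) by pooling squared jump magnitudes over all
#' trajectories at each lag. For free Brownian motion with localization
#' precision eps the expectation is `MSD(t) = d * (2*D*t + 2*eps^2)` in
#' `d` dimensions. For 1D (nanotube) data project positions onto the tube
#' axis first (see [project_to_axis()]); only `x_um` is used when `d = 1`.
#'
#' @param trajs Trajectory table (`traj_id`, `frame`, `x_um`, `y_um`).
#' @param d Dimensionality, 1 or 2.
#' @param max_lag Largest lag in frames (default 50).
#' @param cfg An [acq_config()] (frame interval).
#'
#' @return A tibble with class `"msd_curve"`: `lag`, `t_s`, `msd_um2`,
#'   `n_jumps`; attributes `d`, `frame_interval`. Lags with no jumps are
#'   omitted.
#' @export
compute_msd <- function(trajs, d = 2, max_lag = 50, cfg = acq_config()) {
  stopifnot(d %in% c(1, 2))
  sp <- split(trajs[c("frame", "x_um", "y_um")], trajs$traj_id)
  rows <- purrr::map(seq_len(max_lag), function(L) {
    sq <- unlist(purrr::map(sp, function(tr) {
      o <- order(tr$frame)
      fr <- tr$frame[o]
      i <- seq_len(max(0, length(fr) - L))
      if (length(i) == 0) return(NULL)
      j <- i + L
      ok <- (fr[j] - fr[i]) == L
      if (!any(ok)) return(NULL)
      dx2 <- (tr$x_um[o][j[ok]] - tr$x_um[o][i[ok]])^2
      if (d == 2) dx2 + (tr$y_um[o][j[ok]] - tr$y_um[o][i[ok]])^2 else dx2
    }), use.names = FALSE)
    if (is.null(sq) || length(sq) == 0) return(NULL)
    tibble(lag = L, t_s = L * cfg$frame_interval,
           msd_um2 = mean(sq), n_jumps = length(sq))
  }) |> list_rbind()
  structure(rows, class = c("msd_curve", class(rows)),
            d = d, frame_interval = cfg$frame_interval)
}

#' Fit the linear MSD model
#'
#' Weighted least-squares fit of `MSD(t) = 2*d*D*t + 2*d*eps^2` over the
#' chosen lag range (weights = jump counts per lag). Default lag ranges
#' follow the measurement convention for each geometry: lags 1-5 (first
#' 100 ms) for 1D nanotube diffusion and lags 10-50 (200-1000 ms) for
#' planar-membrane diffusion; lags outside the curve are dropped.
#'
#' @param curve An `"msd_curve"` from [compute_msd()].
#' @param lag_range `c(min, max)` lags in frames; `NULL` picks the default
#'   for the curve's dimensionality.
#'
#' @return One-row tibble: `D_um2_s`, `eps_um`, `d`, `n_lags`, `flag`
#'   (`"ok"`, or `"negative_slope"` when D is floored at 0;
#'   `"negative_intercept"` when eps is floored at 0).
#' @export
fit_msd <- function(curve, lag_range = NULL) {
  d <- attr(curve, "d")
  if (is.null(lag_range)) lag_range <- if (d == 1) c(1, 5) else c(10, 50)
  sub <- curve[curve$lag >= lag_range[1] & curve$lag <= lag_range[2], ]
  if (nrow(sub) < 2) abort("fewer than two MSD points in `lag_range`")
  fit <- lm(msd_um2 ~ t_s, data = sub, weights = sub$n_jumps)
  slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
  flag <- "ok"
  if (slope < 0) { slope <- 0; flag <- "negative_slope" }
  if (icpt < 0) { icpt <- 0; if (flag == "ok") flag <- "negative_intercept" }
  tibble(
    D_um2_s = slope / (2 * d),
    eps_um = sqrt(icpt / (2 * d)),
    d = d, n_lags = nrow(sub), flag = flag
  )
}

#' Project localizations onto a tube axis
#'
#' Rotates coordinates so `x_um` becomes the arclength along the axis and
#' `y_um` the signed transverse offset. With `axis_line = NULL` the major
#' principal axis of the point cloud is used.
#'
#' @param locs Tibble with `x_um`, `y_um`.
#' @param axis_line `c(x0, y0, angle_rad)` or NULL.
#' @return `locs` with projected coordinates.
#' @export
project_to_axis <- function(locs, axis_line = NULL) {
  if (is.null(axis_line)) {
    ctr <- c(mean(locs$x_um), mean(locs$y_um))
    pc <- eigen(cov(cbind(locs$x_um, locs$y_um)))$vectors[, 1]
    axis_line <- c(ctr, atan2(pc[2], pc[1]))
  }
  ang <- axis_line[3]
  dx <- locs$x_um - axis_line[1]; dy <- locs$y_um - axis_line[2]
  locs$x_um <- dx * cos(ang) + dy * sin(ang)
  locs$y_um <- -dx * sin(ang) + dy * cos(ang)
  locs
}

#' Jump magnitudes at a fixed lag
#'
#' @param trajs Trajectory table.
#' @param lag Lag in frames (default 1).
#' @param d Dimensionality (2: planar magnitude; 1: |dx| along `x_um`).
#' @return Numeric vector of jump magnitudes (um).
#' @export
jump_magnitudes <- function(trajs, lag = 1, d = 2) {
  sp <- split(trajs[c("frame", "x_um", "y_um")], trajs$traj_id)
  unlist(purrr::map(sp, function(tr) {
    o <- order(tr$frame)
    fr <- tr$frame[o]
    i <- seq_len(max(0, length(fr) - lag))
    if (length(i) == 0) return(NULL)
    j <- i + lag
    ok <- (fr[j] - fr[i]) == lag
    dx <- tr$x_um[o][j[ok]] - tr$x_um[o][i[ok]]
    if (d == 2) {
      dy <- tr$y_um[o][j[ok]] - tr$y_um[o][i[ok]]
      sqrt(dx^2 + dy^2)
    } else {
      abs(dx)
    }
  }), use.names = FALSE)
}

#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot(object, aes(.data$t_s, .data$msd_um2)) +
    geom_point() + geom_line(alpha = 0.5) +
    labs(x = "lag time (s)", y = expression(MSD ~ (mu * m^2))) +
    theme_minimal()
}
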