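#' Separate immobile from mobile localizations by density clustering
#'
#' Immobile particles produce localization clouds whose extent is limited
#' by the optical precision, while mobile particles spread far between
#' frames. Pooling localizations over `window_frames`-frame windows and
#' clustering them spatially with DBSCAN identifies these precision-limited
#' clouds; clusters whose members span at least `min_lifetime` frames are
#' called immobile, everything else mobile.
#'
#' Defaults follow precision-limited clouds: `eps = 3 * sigma_loc`,
#' `min_samples = 10`, 100-frame windows.
#'
#' @param locs Localization table (`frame`, `x_um`, `y_um`).
#' @param eps DBSCAN neighbourhood radius in um (default `3 * 0.019`).
#' @param min_samples Minimum neighbours (self included) for a core point
#'   (default 10).
#' @param window_frames Frames pooled per clustering window (default 100).
#' @param min_lifetime Minimum frame span of a cluster to call it immobile
#'   (default 50).
#'
#' @return The input tibble with columns `mobility` (`"immobile"` /
#'   `"mobile"`) and `cluster_id` (0 for unclustered) added.
#' @export
filter_immobile <- function(locs, eps = 3 * 0.019, min_samples = 10,
                            window_frames = 100, min_lifetime = 50) {
  if (nrow(locs) == 0) {
    locs$mobility <- character(0)
    locs$cluster_id <- integer(0)
    return(locs)
  }
  locs$.row <- seq_len(nrow(locs))
  win <- locs$frame %/% window_frames
  mobility <- rep("mobile", nrow(locs))
  cluster_id <- rep(0L, nrow(locs))
  offset <- 0L
  for (w in sort(unique(win))) {
    idx <- which(win == w)
    cl <- dbscan_cluster(locs$x_um[idx], locs$y_um[idx], eps, min_samples)
    for (k in setdiff(unique(cl), 0L)) {
      members <- idx[cl == k]
      span <- diff(range(locs$frame[members])) + 1L
      if (span >= min_lifetime) {
        mobility[members] <- "immobile"
        cluster_id[members] <- offset + k
      }
    }
    offset <- offset + max(c(cl, 0L))
  }
  locs$mobility <- mobility
  locs$cluster_id <- cluster_id
  locs$.row <- NULL
  locs
}

# Grid-accelerated DBSCAN on 2D points. Returns integer cluster labels
# (0 = noise). Neighbour queries use a cell hash with cell width eps, so
# only the 3x3 cell neighbourhood is scanned.
dbscan_cluster <- function(x, y, eps, min_samples) {
  n <- length(x)
  if (n == 0) return(integer(0))
  cx <- floor(x / eps); cy <- floor(y / eps)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  cell_of <- match(key, names(cells))

  neighbours <- function(i) {
    out <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(cx[i] + dx, cy[i] + dy)
      cand <- cells[[k]]
      if (!is.null(cand)) out <- c(out, cand)
    }
    d2 <- (x[out] - x[i])^2 + (y[out] - y[i])^2
    out[d2 <= eps^2]
  }

  labels <- rep(NA_integer_, n)   # NA = unvisited, 0 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    nb <- neighbours(i)
    if (length(nb) < min_samples) {
      labels[i] <- 0L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue) > 0) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (!is.na(labels[j]) && labels[j] != 0L) next
      was_noise <- !is.na(labels[j]) && labels[j] == 0L
      labels[j] <- cl
      if (!was_noise || TRUE) {
        nbj <- neighbours(j)
        if (length(nbj) >= min_samples) {
          queue <- c(queue, nbj[is.na(labels[nbj]) | labels[nbj] == 0L])
        }
      }
    }
  }
  labels
}

#' Classify a trajectory as mobile or immobile
#'
#' Fits the linear MSD model to each trajectory's short-lag MSD and calls
#' the trajectory immobile when the fitted diffusion coefficient falls
#' below `d_threshold`. The default threshold 0.05 um^2/s sits an order of
#' magnitude below the slow membrane-spanning population (1 um^2/s) and
#' above the apparent D of precision noise (`sigma_loc^2 / dt` ~= 0.019
#' um^2/s). Trajectories shorter than `min_length` frames are
#' unclassified.
#'
#' @param trajs Linked trajectory table (`traj_id`, `frame`, `x_um`,
#'   `y_um`).
#' @param d_threshold Mobility threshold in um^2/s (default 0.05).
#' @param cfg An [acq_config()] (frame interval).
#' @param d Dimensionality (2 for planar membranes).
#' @param min_length Minimum trajectory length in frames (default 5).
#' @param max_lag Largest lag (frames) used in the per-trajectory MSD fit
#'   (default 4).
#'
#' @return Tibble, one row per trajectory: `traj_id`, `n_frames`, `D_fit`,
#'   `mobility` (`mobile` / `immobile` / `unclassified`).
#' @export
classify_mobility <- function(trajs, d_threshold = 0.05, cfg = acq_config(),
                              d = 2, min_length = 5, max_lag = 4) {
  trajs |>
    group_by(.data$traj_id) |>
    summarise(
      n_frames = dplyr::n(),
      D_fit = traj_msd_d(.data$frame, .data$x_um, .data$y_um,
                         cfg$frame_interval, d, max_lag),
      .groups = "drop"
    ) |>
    mutate(mobility = dplyr::case_when(
      .data$n_frames < min_length ~ "unclassified",
      .data$D_fit < d_threshold ~ "immobile",
      TRUE ~ "mobile"
    ))
}

# slope of MSD(lag) over lags 1..max_lag for one trajectory -> D
traj_msd_d <- function(frame, x, y, dt, d, max_lag) {
  o <- order(frame)
  frame <- frame[o]; x <- x[o]; y <- y[o]
  lags <- seq_len(min(max_lag, length(frame) - 1))
  if (length(lags) == 0) return(NA_real_)
  msd <- vapply(lags, function(L) {
    i <- seq_len(length(frame) - L)
    j <- i + L
    ok <- (frame[j] - frame[i]) == L
    if (!any(ok)) return(NA_real_)
    mean((x[j[ok]] - x[i[ok]])^2 + (y[j[ok]] - y[i[ok]])^2)
  }, double(1))
  ok <- is.finite(msd)
  if (sum(ok) < 2) return(NA_real_)
  slope <- coef(lm(msd[ok] ~ I(lags[ok] * dt)))[2]
  max(unname(slope) / (2 * d), 0)
}
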