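#' Link localizations into trajectories
#'
#' Frame-to-frame particle linking by optimal bipartite assignment
#' (Hungarian algorithm) minimizing total squared displacement, with gap
#' closing: a track missing a detection stays eligible for `max_gap`
#' further frames. Candidate links farther than `max_disp` um per elapsed
#' frame are forbidden; track termination and trajectory birth enter the
#' assignment as alternative costs, so unlinked detections start new
#' trajectories. Every localization ends up in exactly one trajectory.
#'
#' @param locs Localization table (`frame`, `x_um`, `y_um`; other columns
#'   carried along).
#' @param max_disp Maximum linking displacement in um per frame (> 0).
#' @param max_gap Maximum number of missed frames bridged by gap closing
#'   (default 0).
#'
#' @return Tibble of the input rows plus a `traj_id` column, sorted by
#'   `traj_id`, `frame`.
#' @export
#' @examples
#' locs <- sim_planar_trajectories(data.frame(D = 1, fraction = 1), n = 3,
#'                                 cfg = acq_config(rng_seed = 4))
#' trajs <- link_trajectories(locs, max_disp = 1)
#' dplyr::n_distinct(trajs$traj_id)
link_trajectories <- function(locs, max_disp, max_gap = 0) {
  if (max_disp <= 0) abort("`max_disp` must be > 0")
  if (nrow(locs) == 0) {
    locs$traj_id <- integer(0)
    return(locs)
  }
  locs <- arrange(locs, .data$frame)
  row_order <- seq_len(nrow(locs))
  frames <- sort(unique(locs$frame))

  traj_of_row <- integer(nrow(locs))
  next_id <- 1L
  # active track state
  act_id <- integer(0); act_x <- double(0); act_y <- double(0); act_f <- integer(0)

  for (f in frames) {
    det_rows <- which(locs$frame == f)
    dx <- locs$x_um[det_rows]; dy <- locs$y_um[det_rows]
    nd <- length(det_rows)

    live <- act_f >= f - 1L - as.integer(max_gap)
    act_id <- act_id[live]; act_x <- act_x[live]
    act_y <- act_y[live]; act_f <- act_f[live]
    nt <- length(act_id)

    link_to <- rep(0L, nd)  # index into active tracks, 0 = new track
    if (nt > 0 && nd > 0) {
      gapf <- f - act_f
      d2 <- outer(act_x, dx, `-`)^2 + outer(act_y, dy, `-`)^2
      lim2 <- (max_disp * gapf)^2
      alt <- max_disp^2                       # birth / death alternative
      big <- 4 * (max(d2, alt) + 1)
      cc <- d2
      cc[sweep(d2, 1, lim2, `>`)] <- big
      sz <- nt + nd
      mat <- matrix(big, sz, sz)
      mat[seq_len(nt), seq_len(nd)] <- cc
      for (i in seq_len(nt)) mat[i, nd + i] <- alt        # track death
      for (j in seq_len(nd)) mat[nt + j, j] <- alt        # track birth
      mat[seq_len(nd) + nt, seq_len(nt) + nd] <- 0        # complement block
      asg <- hungarian_assign(mat)
      for (i in seq_len(nt)) {
        j <- asg[i]
        if (j >= 1 && j <= nd && mat[i, j] < big) link_to[j] <- i
      }
    }

    for (j in seq_len(nd)) {
      if (nd == 0) break
      if (link_to[j] > 0) {
        i <- link_to[j]
        traj_of_row[det_rows[j]] <- act_id[i]
        act_x[i] <- dx[j]; act_y[i] <- dy[j]; act_f[i] <- f
      } else {
        traj_of_row[det_rows[j]] <- next_id
        act_id <- c(act_id, next_id)
        act_x <- c(act_x, dx[j]); act_y <- c(act_y, dy[j])
        act_f <- c(act_f, f)
        next_id <- next_id + 1L
      }
    }
  }

  locs$traj_id <- traj_of_row
  arrange(locs, .data$traj_id, .data$frame)
}
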