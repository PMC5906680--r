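#' Kymograph along a polyline
#'
#' Samples intensity (image stacks, bilinear interpolation averaged over a
#' transverse width) or localization density (localization tables, binned
#' by arclength within a corridor) along a polyline for every frame,
#' producing a position-by-time array in which static emitters appear as
#' horizontal streaks and directed motion as sloped streaks.
#'
#' @param x An `"image_stack"` array or a localization table.
#' @param polyline Two-column matrix of vertices `(x_um, y_um)`; must have
#'   non-zero length.
#' @param width_px Transverse averaging width in pixels (stacks) or the
#'   corridor width in um is `width_px * cfg$pixel_size` (localizations).
#' @param cfg An [acq_config()] (pixel size; sampling step along the line).
#' @param ... Passed to methods.
#' @return Matrix (positions along line x frames) with class
#'   `"kymograph"`; attribute `step_um` gives the arclength sampling step.
#' @export
kymograph <- function(x, polyline, width_px = 3, cfg = acq_config(), ...) {
  UseMethod("kymograph")
}

# sample points every pixel_size along the polyline; returns positions,
# unit tangents and normals
polyline_samples <- function(polyline, step) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) abort("`polyline` needs at least two vertices")
  seg <- diff(polyline)
  len <- sqrt(rowSums(seg^2))
  if (sum(len) <= 0) abort("`polyline` has zero length")
  pts <- NULL; nrm <- NULL
  for (s in seq_len(nrow(seg))) {
    if (len[s] == 0) next
    t_hat <- seg[s, ] / len[s]
    n_hat <- c(-t_hat[2], t_hat[1])
    d <- seq(0, len[s], by = step)
    p <- cbind(polyline[s, 1] + d * t_hat[1], polyline[s, 2] + d * t_hat[2])
    pts <- rbind(pts, p)
    nrm <- rbind(nrm, matrix(n_hat, nrow(p), 2, byrow = TRUE))
  }
  list(pts = pts, nrm = nrm)
}

bilinear <- function(frame, x_px, y_px) {
  nr <- nrow(frame); nc <- ncol(frame)
  cx <- pmin(pmax(x_px, 0.5), nc - 0.5)
  cy <- pmin(pmax(y_px, 0.5), nr - 0.5)
  j0 <- pmin(pmax(floor(cx - 0.5) + 1L, 1L), nc - 1L)
  i0 <- pmin(pmax(floor(cy - 0.5) + 1L, 1L), nr - 1L)
  fx <- cx - (j0 - 0.5); fy <- cy - (i0 - 0.5)
  frame[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    frame[cbind(i0, j0 + 1L)] * fx * (1 - fy) +
    frame[cbind(i0 + 1L, j0)] * (1 - fx) * fy +
    frame[cbind(i0 + 1L, j0 + 1L)] * fx * fy
}

#' @export
kymograph.image_stack <- function(x, polyline, width_px = 3,
                                  cfg = acq_config(), ...) {
  px <- attr(x, "pixel_size") %||% cfg$pixel_size
  smp <- polyline_samples(polyline, px)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = max(1, width_px)) * px
  nf <- dim(x)[3]
  out <- matrix(0, nrow(smp$pts), nf)
  for (f in seq_len(nf)) {
    frame <- x[, , f]
    acc <- 0
    for (o in offs) {
      qx <- (smp$pts[, 1] + o * smp$nrm[, 1]) / px
      qy <- (smp$pts[, 2] + o * smp$nrm[, 2]) / px
      acc <- acc + bilinear(frame, qx, qy)
    }
    out[, f] <- acc / length(offs)
  }
  structure(out, class = "kymograph", step_um = px)
}

#' @export
kymograph.data.frame <- function(x, polyline, width_px = 3,
                                 cfg = acq_config(), ...) {
  px <- cfg$pixel_size
  smp <- polyline_samples(polyline, px)
  half <- width_px * px / 2
  frames <- sort(unique(x$frame))
  npos <- nrow(smp$pts)
  out <- matrix(0, npos, length(frames))
  # cumulative arclength of sample points
  arc <- c(0, cumsum(sqrt(rowSums(diff(smp$pts)^2))))
  for (k in seq_along(frames)) {
    sub <- x[x$frame == frames[k], ]
    if (nrow(sub) == 0) next
    for (r in seq_len(nrow(sub))) {
      d2 <- (smp$pts[, 1] - sub$x_um[r])^2 + (smp$pts[, 2] - sub$y_um[r])^2
      i <- which.min(d2)
      if (sqrt(d2[i]) <= half) out[i, k] <- out[i, k] + 1
    }
  }
  structure(out, class = "kymograph", step_um = px, arc_um = arc,
            frames = frames)
}

#' @export
autoplot.kymograph <- function(object, ...) {
  df <- expand.grid(pos = seq_len(nrow(object)), frame = seq_len(ncol(object)))
  df$value <- as.vector(object)
  step <- attr(object, "step_um")
  df$pos_um <- (df$pos - 1) * step
  ggplot(df, aes(.data$frame, .data$pos_um, fill = .data$value)) +
    ggplot2::geom_raster() +
    labs(x = "frame", y = "position along line (µm)", fill = "intensity") +
    theme_minimal()
}
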