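#' Estimate a rigid transform between two matched bead sets
#'
#' Least-squares rigid registration (rotation + translation, no scaling) of
#' matched fiducial positions, e.g. multicolour beads visible in both
#' channels, via the SVD (Kabsch) solution. Applying the transform maps
#' channel A coordinates onto channel B.
#'
#' @param beads_a,beads_b Tibbles with `x_um`, `y_um`, matched row by row
#'   (>= 2 pairs).
#' @return A list with class `"rigid_transform2d"`: `angle` (rad),
#'   `translation` (um, length 2), `rms_residual` (um), `degenerate` flag
#'   (set for collinear geometry).
#' @export
estimate_transform <- function(beads_a, beads_b) {
  if (nrow(beads_a) < 2 || nrow(beads_a) != nrow(beads_b))
    abort("need >= 2 matched bead pairs of equal length")
  A <- cbind(beads_a$x_um, beads_a$y_um)
  B <- cbind(beads_b$x_um, beads_b$y_um)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Ac) %*% Bc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  angle <- atan2(R[2, 1], R[1, 1])
  translation <- cb - as.vector(R %*% ca)
  resid <- sweep(A %*% t(R), 2, translation, `+`) - B
  rms <- sqrt(mean(rowSums(resid^2)))
  # collinear (or coincident) geometry leaves the rotation ill-determined
  degenerate <- nrow(A) == 2 || min(svd(Ac)$d) < 1e-12
  structure(list(angle = angle, translation = translation,
                 rms_residual = rms, degenerate = degenerate),
            class = "rigid_transform2d")
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat("<rigid_transform2d>\n")
  cat(sprintf("  rotation    : %.6f rad\n", x$angle))
  cat(sprintf("  translation : (%.4f, %.4f) um\n",
              x$translation[1], x$translation[2]))
  cat(sprintf("  rms residual: %.5f um%s\n", x$rms_residual,
              if (x$degenerate) "  [degenerate geometry]" else ""))
  invisible(x)
}

#' Apply a rigid transform to a localization table
#'
#' @param locs Tibble with `x_um`, `y_um`.
#' @param transform A `"rigid_transform2d"` from [estimate_transform()].
#' @return `locs` with transformed coordinates.
#' @export
apply_transform <- function(locs, transform) {
  R <- matrix(c(cos(transform$angle), sin(transform$angle),
                -sin(transform$angle), cos(transform$angle)), 2, 2)
  xy <- cbind(locs$x_um, locs$y_um) %*% t(R)
  locs$x_um <- xy[, 1] + transform$translation[1]
  locs$y_um <- xy[, 2] + transform$translation[2]
  locs
}

#' Dual-colour co-localization by mutual nearest neighbours
#'
#' Pairs localizations of two channels frame by frame: a pair is reported
#' when each localization is the other's nearest neighbour in its frame and
#' their distance is at most `radius` (default 0.107 um, one pixel).
#' Mutual (rather than one-way) nearest neighbours avoid double counting.
#'
#' @param locs_a,locs_b Localization tables sharing frame indexing.
#' @param radius Co-localization radius in um (default 0.107).
#' @return Tibble `frame`, `row_a`, `row_b` (row numbers in the inputs),
#'   `dist_um`.
#' @export
colocalize <- function(locs_a, locs_b, radius = 0.107) {
  locs_a$.row <- seq_len(nrow(locs_a))
  locs_b$.row <- seq_len(nrow(locs_b))
  frames <- intersect(unique(locs_a$frame), unique(locs_b$frame))
  purrr::map(frames, function(f) {
    a <- locs_a[locs_a$frame == f, ]
    b <- locs_b[locs_b$frame == f, ]
    if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
    # compare on squared distances so an offset equal to the radius is
    # included regardless of sqrt rounding
    d2 <- outer(a$x_um, b$x_um, `-`)^2 + outer(a$y_um, b$y_um, `-`)^2
    nn_ab <- apply(d2, 1, which.min)
    nn_ba <- apply(d2, 2, which.min)
    ia <- which(nn_ba[nn_ab] == seq_len(nrow(a)))
    ib <- nn_ab[ia]
    dist <- sqrt(d2[cbind(ia, ib)])
    keep <- d2[cbind(ia, ib)] <= radius^2
    if (!any(keep)) return(NULL)
    tibble(frame = f, row_a = a$.row[ia[keep]], row_b = b$.row[ib[keep]],
           dist_um = dist[keep])
  }) |> list_rbind()
}
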