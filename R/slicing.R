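# Extraction of the coronal analysis slice.

# Orthonormal slice frame for a bregma->lambda direction. The frame is
# canonical in the anatomical axes (normal points towards positive z,
# in-plane u towards positive x, v towards positive y) so that slices
# defined from either landmark order coincide.
slice_frame <- function(direction, pitch = 0, yaw = 0) {
  n <- direction / sqrt(sum(direction^2))
  if (n[3] < 0) n <- -n
  ex <- c(1, 0, 0)
  u <- ex - sum(ex * n) * n
  if (sqrt(sum(u^2)) < 1e-9)
    stop("bregma-lambda line is dorsoventral: slice frame undefined")
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  if (v[2] < 0) { v <- -v; u <- -u } # keep a right-handed anatomical frame
  if (u[1] < 0) u <- -u
  # declination: pitch tilts the plane about the mediolateral axis v,
  # yaw about the dorsoventral axis u
  rot_axis <- function(axis, deg) {
    th <- deg * pi / 180
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  R <- rot_axis(v, pitch) %*% rot_axis(u, yaw)
  list(n = as.numeric(R %*% n), u = as.numeric(R %*% u),
       v = as.numeric(R %*% v))
}

#' Extract the coronal slice perpendicular to the bregma-lambda line
#'
#' Samples the plane through `bregma + fraction * (lambda - bregma)`,
#' normal to the bregma-lambda direction, on a grid whose pitch equals the
#' voxel size. The default `fraction = 0.25` is the quarter-distance from
#' bregma used by the roundness descriptor. The plane can be tilted by a
#' declination (`pitch` about the mediolateral axis, `yaw` about the
#' dorsoventral axis, degrees) for robustness analyses; the descriptor is
#' expected to tolerate declinations up to about 5 degrees.
#'
#' For an aligned volume (bregma-lambda along z) the slice grid coincides
#' with the volume's (x, y) voxel grid. Interpolation is trilinear;
#' out-of-volume samples are 0. `thickness > 1` averages that many parallel
#' planes spaced one voxel apart.
#'
#' @param v a [volume].
#' @param bregma,lambda 1-based voxel coordinates (3-vectors), e.g. from
#'   [lm_point()].
#' @param fraction position along bregma->lambda, strictly in (0, 1).
#' @param declination numeric 2-vector `c(pitch, yaw)` in degrees.
#' @param thickness number of averaged parallel planes (>= 1).
#' @return A `slice2d`: a matrix (rows = dorsoventral x, columns =
#'   mediolateral y) with attributes `pixel_size` (um) and `provenance`.
#' @export
extract_slice <- function(v, bregma, lambda, fraction = 0.25,
                          declination = c(0, 0), thickness = 1L) {
  assert_volume(v)
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be strictly inside (0, 1)")
  if (all(abs(bregma - lambda) < 1e-9)) stop("bregma and lambda coincide")
  d <- dim(v)
  vs <- voxel_size(v)
  p0 <- bregma + fraction * (lambda - bregma)
  fr <- slice_frame(lambda - bregma, declination[1], declination[2])
  nx <- d[1]; ny <- d[2]
  i <- rep(seq_len(nx), times = ny)
  j <- rep(seq_len(ny), each = nx)
  base <- cbind(p0[1] + (i - p0[1]) * fr$u[1] + (j - p0[2]) * fr$v[1],
                p0[2] + (i - p0[1]) * fr$u[2] + (j - p0[2]) * fr$v[2],
                p0[3] + (i - p0[1]) * fr$u[3] + (j - p0[2]) * fr$v[3])
  acc <- numeric(nx * ny)
  offs <- seq_len(thickness) - (thickness + 1) / 2
  any_inside <- FALSE
  for (o in offs) {
    pts <- base + matrix(fr$n, nrow(base), 3, byrow = TRUE) * o
    inside <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
      pts[, 2] >= 1 & pts[, 2] <= d[2] &
      pts[, 3] >= 1 & pts[, 3] <= d[3]
    any_inside <- any_inside || any(inside)
    acc <- acc + sample_volume_trilinear(v, pts)
  }
  if (!any_inside) stop("slice plane misses the volume")
  s <- matrix(acc / thickness, nx, ny)
  structure(s,
            pixel_size = vs,
            bit_depth = bit_depth(v),
            provenance = list(fraction = fraction,
                              declination = as.numeric(declination),
                              thickness = thickness,
                              bregma = as.numeric(bregma),
                              lambda = as.numeric(lambda)),
            class = c("slice2d", "matrix", "array"))
}

#' @export
print.slice2d <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf(
    "<slice2d> %d x %d px, %.4g um/px, fraction %.3g, declination (%g, %g) deg\n",
    nrow(x), ncol(x), attr(x, "pixel_size"), pr$fraction,
    pr$declination[1], pr$declination[2]))
  invisible(x)
}
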