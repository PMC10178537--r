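# Outer-surface point cloud and axis-aligned ellipse fit: the roundness
# descriptor b/a of the calvarial cross-section.

#' Collect the outer calvarial surface as a 2D point cloud
#'
#' For every mediolateral column of the slice between the left and right
#' parietal edges, the dorsal-most threshold crossing along x is emitted as
#' one surface point. The crossing is localised with sub-pixel precision by
#' linear interpolation between the voxels bracketing the threshold.
#' Columns with no crossing are skipped (their count is reported in the
#' `n_skipped` attribute).
#'
#' @param s a `slice2d` from [extract_slice()].
#' @param left_edge,right_edge parietal edge positions: 2-vectors `(x, y)`
#'   in micrometres in slice coordinates (only the y component bounds the
#'   column range).
#' @param threshold intensity threshold; Otsu's threshold of the slice by
#'   default.
#' @return A `point_cloud2d`: data frame with columns `x`, `y` (um) and
#'   attributes `n_skipped` and `provenance`.
#' @export
detect_outer_surface <- function(s, left_edge, right_edge, threshold = NULL) {
  if (!inherits(s, "slice2d")) stop("`s` must be a slice2d")
  px <- attr(s, "pixel_size")
  if (is.null(threshold))
    threshold <- otsu_threshold(s, attr(s, "bit_depth") %||% 16L)
  y_lo <- min(left_edge[2], right_edge[2])
  y_hi <- max(left_edge[2], right_edge[2])
  if (abs(y_hi - y_lo) < px) stop("degenerate parietal edge pair")
  j_range <- seq(max(1L, ceiling(um_to_vox(y_lo, px))),
                 min(ncol(s), floor(um_to_vox(y_hi, px))))
  xs <- ys <- numeric(0)
  skipped <- 0L
  for (j in j_range) {
    col <- s[, j]
    hit <- which(col >= threshold)
    if (length(hit) == 0) { skipped <- skipped + 1L; next }
    i <- hit[1]
    if (i == 1) {
      xf <- 1
    } else {
      # sub-pixel crossing between i-1 and i
      xf <- (i - 1) + (threshold - col[i - 1]) / (col[i] - col[i - 1])
    }
    xs <- c(xs, vox_to_um(xf, px))
    ys <- c(ys, vox_to_um(j, px))
  }
  if (length(xs) < 5)
    stop("insufficient surface: only ", length(xs), " points found")
  structure(data.frame(x = xs, y = ys),
            n_skipped = skipped,
            provenance = attr(s, "provenance"),
            class = c("point_cloud2d", "data.frame"))
}

#' Least-squares fit of an axis-aligned ellipse
#'
#' Fits `((X - X0)/a)^2 + ((Y - Y0)/b)^2 = 1` to a point cloud by linear
#' least squares on the algebraic form `A x^2 + B y^2 + C x + D y + E = 0`
#' under the normalisation `A + B = 1`, then recovers centre and semi-axes
#' by completing the square. The model has no cross term: skulls are
#' pre-aligned, so the ellipse axes coincide with the anatomical axes by
#' construction, and the fit is a deterministic closed form.
#'
#' @param pc a `point_cloud2d`, data frame or 2-column matrix of `(x, y)`
#'   points in micrometres; at least 5 non-collinear points.
#' @return An `ellipse_fit`: list with `center` (`c(X0, Y0)`, um), `a`
#'   (dorsoventral semi-axis, um), `b` (mediolateral semi-axis, um),
#'   `rms_residual` (RMS of the normalised algebraic residual) and
#'   `n_points`.
#' @export
fit_axis_aligned_ellipse <- function(pc) {
  pts <- as.matrix(as.data.frame(pc)[, c("x", "y")])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 5) stop("at least 5 points are required to fit an ellipse")
  x <- pts[, 1]; y <- pts[, 2]
  # A (x^2 - y^2) + C x + D y + E = -y^2   (B = 1 - A)
  M <- cbind(x^2 - y^2, x, y, 1)
  if (qr(M)$rank < 4) stop("degenerate conic: collinear points")
  beta <- qr.solve(M, -y^2)
  A <- beta[1]; B <- 1 - A; C <- beta[2]; D <- beta[3]; E <- beta[4]
  if (A <= 0 || B <= 0) stop("degenerate conic: fitted quadratic not an ellipse")
  X0 <- -C / (2 * A); Y0 <- -D / (2 * B)
  FF <- A * X0^2 + B * Y0^2 - E
  if (FF <= 0) stop("degenerate conic: non-positive squared semi-axes")
  a <- sqrt(FF / A); b <- sqrt(FF / B)
  res <- ((x - X0) / a)^2 + ((y - Y0) / b)^2 - 1
  structure(list(center = c(X0 = unname(X0), Y0 = unname(Y0)),
                 a = unname(a), b = unname(b),
                 rms_residual = sqrt(mean(res^2)),
                 n_points = n,
                 axis_labels = c(a = "dorsoventral (x)",
                                 b = "mediolateral (y)")),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> center (%.4g, %.4g) um, a = %.6g um (dorsoventral), b = %.6g um (mediolateral)\n  b/a = %.6g, rms residual %.3g, n = %d\n",
    x$center[1], x$center[2], x$a, x$b, x$b / x$a, x$rms_residual,
    x$n_points))
  invisible(x)
}

#' Roundness descriptor of a fitted ellipse
#'
#' The ratio of the mediolateral semi-axis `b` to the dorsoventral
#' semi-axis `a`. A circular cross-section gives 1; mouse calvariae are
#' wider than tall, so healthy values exceed 1, and rounder (more domed)
#' cross-sections move towards 1.
#'
#' @param f an `ellipse_fit`.
#' @return The dimensionless ratio `b / a`.
#' @export
roundness <- function(f) {
  if (!inherits(f, "ellipse_fit")) stop("`f` must be an ellipse_fit")
  f$b / f$a
}

#' Slice, detect and fit in one call
#'
#' Convenience wrapper running the quarter-slice extraction, outer-surface
#' detection between the parietal edges and the axis-aligned ellipse fit on
#' an aligned skull.
#'
#' @param v an aligned [volume].
#' @param lm its [landmark_set]: bregma, lambda and both parietal edges.
#' @param fraction,declination passed to [extract_slice()].
#' @param threshold passed to [detect_outer_surface()].
#' @return An `ellipse_fit`.
#' @export
slice_and_fit <- function(v, lm, fraction = 0.25, declination = c(0, 0),
                          threshold = NULL) {
  b <- lm_point(lm, "bregma"); l <- lm_point(lm, "lambda")
  s <- extract_slice(v, b, l, fraction, declination)
  vs <- voxel_size(v)
  le <- lm_point(lm, "parietal_edge_left")
  re <- lm_point(lm, "parietal_edge_right")
  pc <- detect_outer_surface(s,
                             vox_to_um(le[1:2], vs),
                             vox_to_um(re[1:2], vs),
                             threshold = threshold)
  fit_axis_aligned_ellipse(pc)
}

#' Declination robustness sweep
#'
#' Re-runs the slice extraction, surface detection and ellipse fit over a
#' set of plane declinations and tabulates the roundness descriptor. Used
#' to demonstrate that the descriptor is robust to small deviations
#' (up to +/-5 degrees) of the slicing plane from perpendicularity to the
#' bregma-lambda line.
#'
#' @param v an aligned [volume].
#' @param lm its [landmark_set] (bregma, lambda and both parietal edges).
#' @param angles data frame with columns `pitch` and `yaw` (degrees), or a
#'   numeric vector of pitch angles (yaw 0).
#' @param fraction slice position, default 1/4 from bregma.
#' @param limit reject angles with magnitude above this bound (degrees).
#' @return A data frame `pitch, yaw, a, b, b_over_a`, sorted by angle.
#' @export
declination_sweep <- function(v, lm, angles = seq(-5, 5), fraction = 0.25,
                              limit = 5) {
  if (!is.data.frame(angles))
    angles <- data.frame(pitch = angles, yaw = 0)
  if (any(abs(c(angles$pitch, angles$yaw)) > limit + 1e-9))
    stop("declination angles exceed the configured limit of ", limit,
         " degrees")
  angles <- angles[order(angles$pitch, angles$yaw), , drop = FALSE]
  out <- lapply(seq_len(nrow(angles)), function(i) {
    f <- slice_and_fit(v, lm, fraction,
                       c(angles$pitch[i], angles$yaw[i]))
    data.frame(pitch = angles$pitch[i], yaw = angles$yaw[i],
               a = f$a, b = f$b, b_over_a = roundness(f))
  })
  do.call(rbind, out)
}
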