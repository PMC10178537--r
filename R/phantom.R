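# Synthetic skull phantoms.
#
# The phantom is a half-ellipsoid shell: the minimal geometry that carries
# every feature the morphometric pipeline touches (a domed outer surface
# between parietal edges, bregma/lambda landmarks on the dorsal midline, a
# well-defined cross-sectional ellipse). It is not an anatomical skull.

#' Specification of a skull phantom
#'
#' Defines a half-ellipsoid calvarial shell with known ground truth. The
#' generating ellipsoid has semi-axes `semi_axis_dv` (a, dorsoventral),
#' `semi_axis_ml` (b, mediolateral) and `semi_axis_ap` (c, anteroposterior);
#' every cross-section perpendicular to the anteroposterior axis is an
#' ellipse with the same b/a ratio, so the phantom's true roundness is
#' `semi_axis_ml / semi_axis_dv` irrespective of pose.
#'
#' Defaults emulate an adult mouse calvaria scanned at 15 um: dome
#' half-height 3 mm, half-width 4.5 mm (truth b/a = 1.5), bregma-lambda
#' span 4.3 mm, shell thickness 150 um.
#'
#' @param semi_axis_dv,semi_axis_ml,semi_axis_ap outer semi-axes, um.
#' @param shell_thickness bone shell thickness, um; must be smaller than
#'   the smallest semi-axis and at least one voxel.
#' @param voxel_size isotropic voxel size, um.
#' @param pose list with `translation` (3-vector, um), `rotation`
#'   (`c(horizontal, sagittal)` degrees) and `scale` (> 0), applied to the
#'   phantom before voxelisation.
#' @param noise_sd additive Gaussian intensity noise (clipped to the bit
#'   range).
#' @param bit_depth 8 or 16.
#' @param bone_intensity,background mean intensities of shell and
#'   surroundings (scanner contrast is a free parameter of the phantom).
#' @param landmark_frac bregma/lambda are placed on the outer dorsal
#'   surface at this fraction of the anteroposterior semi-axis (default
#'   0.95; the exact poles are tangent points that no edge detector can
#'   recover).
#' @param ventral_extent how far past the equator (as a fraction of the
#'   dorsoventral semi-axis) the shell continues ventrally.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(semi_axis_dv = 3000, semi_axis_ml = 4500,
                         semi_axis_ap = 2150, shell_thickness = 150,
                         voxel_size = 15,
                         pose = list(translation = c(0, 0, 0),
                                     rotation = c(horizontal = 0, sagittal = 0),
                                     scale = 1),
                         noise_sd = 0, bit_depth = 16L,
                         bone_intensity = NULL, background = NULL,
                         landmark_frac = 0.95, ventral_extent = 0.15,
                         seed = 1L) {
  ax <- c(semi_axis_dv, semi_axis_ml, semi_axis_ap)
  if (any(ax <= 0) || shell_thickness <= 0)
    stop("semi-axes and shell thickness must be positive")
  if (shell_thickness >= min(ax))
    stop("shell thickness must be smaller than the smallest semi-axis")
  if (shell_thickness < voxel_size)
    stop("unresolvable shell: thinner than one voxel")
  pose$translation <- pose$translation %||% c(0, 0, 0)
  pose$rotation <- pose$rotation %||% c(horizontal = 0, sagittal = 0)
  if (is.null(names(pose$rotation)))
    names(pose$rotation) <- c("horizontal", "sagittal")[seq_along(pose$rotation)]
  pose$rotation <- c(horizontal = unname(pose$rotation["horizontal"] %|na|% 0),
                     sagittal = unname(pose$rotation["sagittal"] %|na|% 0))
  pose$scale <- pose$scale %||% 1
  if (pose$scale <= 0) stop("pose scale must be positive")
  maxval <- 2^bit_depth - 1
  structure(list(
    semi_axis_dv = semi_axis_dv, semi_axis_ml = semi_axis_ml,
    semi_axis_ap = semi_axis_ap, shell_thickness = shell_thickness,
    voxel_size = voxel_size, pose = pose, noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth),
    bone_intensity = bone_intensity %||% round(0.75 * maxval),
    background = background %||% round(0.05 * maxval),
    landmark_frac = landmark_frac, ventral_extent = ventral_extent,
    seed = as.integer(seed)), class = "phantom_spec")
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

# 3D pose rotation: horizontal rotation about the x axis composed with
# sagittal rotation about the y axis (unposed -> posed).
pose_rotation <- function(rotation) {
  th <- rotation[["horizontal"]] * pi / 180
  ts <- rotation[["sagittal"]] * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(th), sin(th),
                 0, -sin(th), cos(th)), 3, 3)
  Ry <- matrix(c(cos(ts), 0, -sin(ts),
                 0, 1, 0,
                 sin(ts), 0, cos(ts)), 3, 3)
  Rx %*% Ry
}

#' Generate a skull phantom volume with known ground truth
#'
#' Voxelises the half-ellipsoid shell described by a [phantom_spec] in the
#' requested pose. The shell is evaluated analytically at every voxel
#' centre (the pose is inverted exactly rather than resampled, so the posed
#' phantom carries no interpolation blur). Landmarks are returned both in
#' the posed frame (pipeline input) and the unposed frame (ground truth for
#' alignment tests), together with the exact axis-aligned ellipse of the
#' outer cross-section at the quarter bregma-lambda slice.
#'
#' @param spec a [phantom_spec].
#' @return A list: `volume` (posed [volume]), `landmarks` (posed
#'   [landmark_set]), `landmarks_true` (unposed), `truth` (list with
#'   `center` um, `a`, `b`, `b_over_a`, `slice_z` voxel), `spec`.
#' @export
make_skull_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size
  a <- spec$semi_axis_dv / vs
  b <- spec$semi_axis_ml / vs
  cc <- spec$semi_axis_ap / vs
  th <- spec$shell_thickness / vs
  ve <- spec$ventral_extent
  s <- spec$pose$scale
  R <- pose_rotation(spec$pose$rotation)
  tr <- spec$pose$translation / vs

  # bounding corners of the dome in the centred unposed frame (voxels)
  corners <- as.matrix(expand.grid(x = c(-a, ve * a), y = c(-b, b),
                                   z = c(-cc, cc)))
  posed_corners <- t(s * R %*% t(corners)) +
    matrix(tr, nrow(corners), 3, byrow = TRUE)
  pad <- 6
  lo <- floor(apply(posed_corners, 2, min)) - pad
  hi <- ceiling(apply(posed_corners, 2, max)) + pad
  dims <- as.integer(hi - lo + 1)
  center <- 1 - lo # voxel index of the unposed origin

  Rinv <- t(R)
  maxval <- 2^spec$bit_depth - 1
  a_in <- a - th; b_in <- b - th; c_in <- cc - th
  arr <- with_seed(spec$seed,
                   .phantom_fill_cpp(dims, center, tr, Rinv, s,
                                     a, b, cc, a_in, b_in, c_in, ve,
                                     spec$bone_intensity, spec$background,
                                     spec$noise_sd, maxval))
  v <- new_volume(arr, vs, spec$bit_depth)

  # landmarks in the centred unposed frame (voxels)
  qf <- spec$landmark_frac
  x_lm <- -a * sqrt(1 - qf^2)
  f <- 0.25
  z_star <- qf * cc * (1 - 2 * f)
  g <- sqrt(1 - (z_star / cc)^2)
  pts_true <- rbind(bregma = c(x_lm, 0, qf * cc),
                    lambda = c(x_lm, 0, -qf * cc),
                    parietal_edge_left = c(0, -g * b, z_star),
                    parietal_edge_right = c(0, g * b, z_star))
  to_index <- function(p) p + center
  lm_true <- landmark_set("truth", t(apply(pts_true, 1, to_index)))
  posed <- t(s * R %*% t(pts_true)) + matrix(tr, 4, 3, byrow = TRUE)
  rownames(posed) <- rownames(pts_true)
  lm_posed <- landmark_set("phantom", t(apply(posed, 1, to_index)))

  truth <- list(
    center = vox_to_um(c(center[1], center[2]), vs),
    a = g * spec$semi_axis_dv,
    b = g * spec$semi_axis_ml,
    b_over_a = spec$semi_axis_ml / spec$semi_axis_dv,
    slice_z = z_star + center[3],
    fraction = f)
  list(volume = v, landmarks = lm_posed, landmarks_true = lm_true,
       truth = truth, spec = spec)
}

#' Sample noisy points from an axis-aligned ellipse arc
#'
#' Unit-test input for the ellipse estimator: `n` points evenly spaced in
#' parameter angle over `arc`, plus isotropic Gaussian coordinate noise.
#' The default arc is the dorsal half (the part of the calvaria the
#' surface detector sees).
#'
#' @param a,b semi-axes (a along x, b along y), um.
#' @param center 2-vector, um.
#' @param arc angular range in radians (parametric angle).
#' @param n number of points (>= 5).
#' @param noise_sd isotropic Gaussian noise sd, um.
#' @param seed RNG seed.
#' @return A `point_cloud2d` data frame with columns `x`, `y`.
#' @export
make_ellipse_point_cloud <- function(a, b, center = c(0, 0),
                                     arc = c(pi / 2, 3 * pi / 2), n = 200,
                                     noise_sd = 0, seed = 1L) {
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  if (n < 5) stop("at least 5 points are required (ellipse under-determined)")
  theta <- seq(arc[1], arc[2], length.out = n)
  pts <- cbind(x = center[1] + a * cos(theta),
               y = center[2] + b * sin(theta))
  if (noise_sd > 0)
    pts <- pts + with_seed(seed,
                           matrix(stats::rnorm(2 * n, sd = noise_sd), n, 2))
  structure(as.data.frame(pts), class = c("point_cloud2d", "data.frame"))
}
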