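# Plane-constrained 2D similarity transforms.
#
# The alignment protocol computes shape-preserving transforms (translation,
# rotation, uniform scale) in one anatomical plane and applies them to the
# whole 3D volume. Plane axis pairs, in volume dimension order (x = dim 1
# dorsoventral, y = dim 2 mediolateral, z = dim 3 anteroposterior):
#   horizontal: (y, z)   sagittal: (x, z)   coronal: (x, y)
plane_dims <- function(plane) {
  switch(plane,
         horizontal = c(2L, 3L),
         sagittal   = c(1L, 3L),
         coronal    = c(1L, 2L),
         stop("unknown plane: ", plane))
}

#' 2D similarity transform in an anatomical plane
#'
#' Acts on points `p` (in micrometres, ordered as the plane's axis pair) as
#' `p' = scale * R(rotation) %*% p + translation`. Similarities preserve
#' angles and distance ratios, so applying one to a skull leaves its shape
#' unchanged.
#'
#' @param plane `"horizontal"` (y-z), `"sagittal"` (x-z) or `"coronal"`
#'   (x-y).
#' @param rotation counter-clockwise rotation in degrees.
#' @param scale uniform scale factor (> 0).
#' @param translation numeric 2-vector, micrometres.
#' @return An object of class `similarity2d`.
#' @export
similarity2d <- function(plane, rotation = 0, scale = 1,
                         translation = c(0, 0)) {
  plane <- match.arg(plane, c("horizontal", "sagittal", "coronal"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("`scale` must be a single positive number")
  if (length(translation) != 2) stop("`translation` must be a 2-vector (um)")
  structure(list(plane = plane, rotation = rotation, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity2d")
}

#' @export
print.similarity2d <- function(x, ...) {
  cat(sprintf("<similarity2d %s> rotation %.4g deg, scale %.6g, translation (%.4g, %.4g) um\n",
              x$plane, x$rotation, x$scale, x$translation[1],
              x$translation[2]))
  invisible(x)
}

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a 2D similarity to points
#' @param t a [similarity2d].
#' @param pts n x 2 matrix of points (um) in the transform's plane.
#' @return n x 2 matrix of transformed points.
#' @export
transform_points <- function(t, pts) {
  pts <- rbind(pts)
  res <- t$scale * pts %*% t(rot2(t$rotation))
  res[, 1] <- res[, 1] + t$translation[1]
  res[, 2] <- res[, 2] + t$translation[2]
  res
}

#' Compose two similarities in the same plane
#' @param a,b [similarity2d] objects; the result applies `b` first, then `a`.
#' @return A [similarity2d] (the class is closed under composition).
#' @export
compose_similarity2d <- function(a, b) {
  if (a$plane != b$plane) stop("cannot compose transforms in different planes")
  similarity2d(a$plane,
               rotation = a$rotation + b$rotation,
               scale = a$scale * b$scale,
               translation = as.numeric(
                 a$scale * rot2(a$rotation) %*% b$translation) +
                 a$translation)
}

invert_similarity2d <- function(t) {
  similarity2d(t$plane, rotation = -t$rotation, scale = 1 / t$scale,
               translation = as.numeric(
                 -(1 / t$scale) * rot2(-t$rotation) %*% t$translation))
}

#' Estimate the similarity mapping two landmarks onto two others
#'
#' Two labelled point pairs fully determine a 2D similarity; the closed
#' form (complex ratio of the point differences) maps the defining
#' landmarks exactly, which the alignment protocol relies on when
#' superimposing bregma-lambda lines.
#'
#' @param moving,reference 2 x 2 matrices; rows are the two corresponding
#'   points (um) in the plane's axis order.
#' @param plane the anatomical plane the transform acts in.
#' @return A [similarity2d] `t` with `transform_points(t, moving) ==
#'   reference` to numerical precision.
#' @export
estimate_similarity_2d <- function(moving, reference, plane = "horizontal") {
  moving <- rbind(moving); reference <- rbind(reference)
  stopifnot(nrow(moving) == 2, nrow(reference) == 2,
            ncol(moving) == 2, ncol(reference) == 2)
  m <- complex(real = moving[, 1], imaginary = moving[, 2])
  r <- complex(real = reference[, 1], imaginary = reference[, 2])
  if (abs(m[2] - m[1]) < 1e-12 || abs(r[2] - r[1]) < 1e-12)
    stop("degenerate landmark pair")
  alpha <- (r[2] - r[1]) / (m[2] - m[1])
  beta <- r[1] - alpha * m[1]
  similarity2d(plane,
               rotation = Arg(alpha) * 180 / pi,
               scale = Mod(alpha),
               translation = c(Re(beta), Im(beta)))
}

# Bilinear / nearest gathers from a matrix-organised volume (`m` is
# n_orth x n1*n2 with the transform plane flattened into columns); the
# kernels live in src/resample.cpp, as the inner loop touches every voxel.
gather_bilinear <- function(m, n1, n2, u, v) {
  .gather_bilinear_cpp(m, n1, n2, u, v)
}

gather_nearest <- function(m, n1, n2, u, v) {
  .gather_nearest_cpp(m, n1, n2, u, v)
}

#' Resample a volume under a plane-constrained similarity
#'
#' The 2D transform is applied identically to every slice along the axis
#' orthogonal to its plane, the way the alignment protocol propagates a
#' transform estimated in the horizontal plane through the whole scan.
#' Out-of-bounds voxels are filled with 0.
#'
#' With `orthogonal_scale = TRUE` the transform's uniform scale also acts
#' on the orthogonal axis (about the volume centre), making the operation a
#' genuine 3D similarity with in-plane rotation; [align_skull()] uses this
#' so that skull size is normalised in all three axes, not just two.
#'
#' @param v a [volume].
#' @param t a [similarity2d].
#' @param interpolation `"linear"` (default) or `"nearest"`; nearest is
#'   exact for integer-voxel translations.
#' @param orthogonal_scale also scale the orthogonal axis by `t$scale`.
#' @return A [volume] with the same dimensions and metadata.
#' @export
apply_transform_to_volume <- function(v, t,
                                      interpolation = c("linear", "nearest"),
                                      orthogonal_scale = FALSE) {
  assert_volume(v)
  interpolation <- match.arg(interpolation)
  vs <- voxel_size(v)
  dims <- dim(v)
  pd <- plane_dims(t$plane)
  orth <- setdiff(1:3, pd)
  # arrange the volume as (orth, plane1, plane2)
  perm <- c(orth, pd)
  m <- if (identical(perm, 1:3)) unclass(v) else aperm(unclass(v), perm)
  n_orth <- dims[orth]; n1 <- dims[pd[1]]; n2 <- dims[pd[2]]
  dim(m) <- c(n_orth, n1 * n2)
  storage.mode(m) <- "double"

  # output plane grid in um -> source coordinates via the inverse transform
  inv <- invert_similarity2d(t)
  g1 <- vox_to_um(seq_len(n1), vs)
  g2 <- vox_to_um(seq_len(n2), vs)
  pts <- cbind(rep(g1, times = n2), rep(g2, each = n1))
  src <- transform_points(inv, pts)
  u <- um_to_vox(src[, 1], vs)
  vv <- um_to_vox(src[, 2], vs)

  if (orthogonal_scale && t$scale != 1) {
    mid <- (n_orth + 1) / 2
    src_orth <- mid + (seq_len(n_orth) - mid) / t$scale
    if (interpolation == "nearest") {
      i0 <- round(src_orth)
      ok <- i0 >= 1 & i0 <= n_orth
      m2 <- m[ifelse(ok, i0, 1), , drop = FALSE]
      if (any(!ok)) m2[!ok, ] <- 0
      m <- m2
    } else {
      i0 <- floor(src_orth); fi <- src_orth - i0
      clamp <- function(i) pmin(pmax(i, 1L), n_orth)
      ok0 <- i0 >= 1 & i0 <= n_orth
      ok1 <- (i0 + 1) >= 1 & (i0 + 1) <= n_orth
      m2 <- m[clamp(i0), , drop = FALSE] * ((1 - fi) * ok0) +
        m[clamp(i0 + 1), , drop = FALSE] * (fi * ok1)
      m <- m2
    }
  }

  res <- if (interpolation == "linear") gather_bilinear(m, n1, n2, u, vv)
  else gather_nearest(m, n1, n2, u, vv)

  # interpolation weights are convex, so the result stays in the bit range
  if (is.integer(unclass(v))) # keep quantised volumes quantised
    res <- .round_to_int_cpp(res)
  dim(res) <- c(n_orth, n1, n2)
  out <- if (identical(perm, 1:3)) res else aperm(res, order(perm))
  new_volume(out, vs, bit_depth(v))
}

# Map a landmark (1-based voxel coords, length 3) through a plane
# transform; with orthogonal_scale the orthogonal coordinate scales about
# the volume centre, matching apply_transform_to_volume().
transform_landmark <- function(p, t, vs, dims, orthogonal_scale = FALSE) {
  pd <- plane_dims(t$plane)
  orth <- setdiff(1:3, pd)
  xy <- vox_to_um(p[pd], vs)
  xy2 <- transform_points(t, rbind(xy))[1, ]
  p[pd] <- um_to_vox(xy2, vs)
  if (orthogonal_scale) {
    mid <- (dims[orth] + 1) / 2
    p[orth] <- mid + (p[orth] - mid) * t$scale
  }
  p
}

# Trilinear interpolation of `v` at an n x 3 matrix of fractional 1-based
# voxel coordinates; out-of-bounds samples are 0.
sample_volume_trilinear <- function(v, coords) {
  d <- dim(v)
  vv <- unclass(v)
  dim(vv) <- NULL
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(coords))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3] &
      w > 0
    if (any(ok)) {
      idx <- xi[ok] + (yi[ok] - 1) * d[1] + (zi[ok] - 1) * d[1] * d[2]
      val[ok] <- val[ok] + w[ok] * vv[idx]
    }
  }
  val
}
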