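# Landmark-constrained skull alignment.
#
# Each skull is aligned to a nominated reference in two stages: a 2D
# similarity estimated in the horizontal (y-z) plane from the bregma and
# lambda landmarks, applied to the whole volume, followed by automatic
# recovery of the landmark heights (dorsoventral coordinate) by edge
# detection and a secondary similarity in the sagittal (x-z) plane.

# Otsu threshold of an intensity array on its native scale, from the exact
# integer histogram (single pass, no copy of the volume: the arrays here
# can run to tens of millions of voxels).
otsu_threshold <- function(x, bit_depth = 16L) {
  maxval <- 2^bit_depth - 1
  counts <- as.numeric(tabulate(as.integer(x) + 1L, nbins = maxval + 1))
  lev <- as.numeric(0:maxval)
  w0 <- cumsum(counts)
  w1 <- sum(counts) - w0
  s0 <- cumsum(counts * lev)
  mu0 <- s0 / w0
  mu1 <- (s0[length(s0)] - s0) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!is.finite(between)] <- -Inf
  t_lev <- lev[which.max(between)]
  t_lev + 0.5 # crossings are "rises through" the class boundary
}

#' Recover the dorsoventral height of a landmark by edge detection
#'
#' Scans the dorsoventral column at a given (y, z) position from the dorsal
#' side (x index 1) ventrally and returns the first threshold crossing,
#' i.e. the outer bone surface. The landmark protocol places bregma and
#' lambda on the dorsal surface, so this crossing is the landmark height.
#'
#' @param v a [volume].
#' @param yz numeric 2-vector: (y, z) in 1-based voxel coordinates
#'   (rounded to the nearest column).
#' @param threshold intensity threshold; by default Otsu's threshold of the
#'   whole volume (a per-slice threshold degenerates on slices that contain
#'   no bone).
#' @return The 1-based x voxel index of the crossing (1 when the column
#'   starts at or above threshold, i.e. the surface sits at the dorsal
#'   boundary).
#' @export
recover_landmark_height <- function(v, yz, threshold = NULL) {
  assert_volume(v)
  d <- dim(v)
  j <- round(yz[1]); k <- round(yz[2])
  if (j < 1 || j > d[2] || k < 1 || k > d[3])
    stop("column outside the volume")
  if (is.null(threshold))
    threshold <- otsu_threshold(v, bit_depth(v))
  col <- as.numeric(v[, j, k])
  hit <- which(col >= threshold)
  if (length(hit) == 0) stop("no surface at column (", j, ", ", k, ")")
  hit[1]
}

#' Align a skull to a reference via bregma-lambda landmarks
#'
#' Implements the two-stage protocol: (1) a similarity estimated in the
#' horizontal plane maps the skull's (bregma, lambda) onto the reference's
#' and is applied to the full volume (with its uniform scale also applied
#' dorsoventrally, so size is normalised in three axes); (2) landmark
#' heights are recovered by edge detection on the realigned volume and a
#' secondary similarity in the sagittal plane aligns the (height, z) pairs.
#' After both stages the skull's bregma and lambda coincide with the
#' reference's to within about one voxel (the height-recovery resolution).
#'
#' @param v a [volume].
#' @param lm [landmark_set] of `v` (must contain bregma and lambda).
#' @param ref reference [landmark_set] in the target frame, same voxel size.
#' @param interpolation passed to [apply_transform_to_volume()].
#' @param threshold optional fixed edge-detection threshold.
#' @return A list with elements `volume` (aligned), `landmarks` (updated
#'   [landmark_set]) and `transforms` (the horizontal and sagittal
#'   [similarity2d] objects).
#' @export
align_skull <- function(v, lm, ref, interpolation = "linear",
                        threshold = NULL) {
  assert_volume(v)
  vs <- voxel_size(v)
  dims <- dim(v)
  for (nm in c("bregma", "lambda")) {
    lm_point(lm, nm); lm_point(ref, nm)
  }
  mv_b <- lm_point(lm, "bregma"); mv_l <- lm_point(lm, "lambda")
  rf_b <- lm_point(ref, "bregma"); rf_l <- lm_point(ref, "lambda")

  # stage 1: horizontal plane (y, z), scale propagated to x
  t_h <- estimate_similarity_2d(
    moving    = vox_to_um(rbind(mv_b[2:3], mv_l[2:3]), vs),
    reference = vox_to_um(rbind(rf_b[2:3], rf_l[2:3]), vs),
    plane = "horizontal")
  v1 <- apply_transform_to_volume(v, t_h, interpolation,
                                  orthogonal_scale = TRUE)
  lm1 <- lm
  for (nm in lm$name)
    lm1 <- lm_replace(lm1, nm, transform_landmark(lm_point(lm, nm), t_h, vs,
                                                  dims,
                                                  orthogonal_scale = TRUE))

  # stage 2: recover heights on the realigned volume, then sagittal plane
  b1 <- lm_point(lm1, "bregma"); l1 <- lm_point(lm1, "lambda")
  hb <- recover_landmark_height(v1, b1[2:3], threshold)
  hl <- recover_landmark_height(v1, l1[2:3], threshold)
  t_s <- estimate_similarity_2d(
    moving    = vox_to_um(rbind(c(hb, b1[3]), c(hl, l1[3])), vs),
    reference = vox_to_um(rbind(rf_b[c(1, 3)], rf_l[c(1, 3)]), vs),
    plane = "sagittal")
  v2 <- apply_transform_to_volume(v1, t_s, interpolation)
  lm2 <- lm_replace(lm1, "bregma", c(hb, b1[2:3]))
  lm2 <- lm_replace(lm2, "lambda", c(hl, l1[2:3]))
  for (nm in lm2$name)
    lm2 <- lm_replace(lm2, nm, transform_landmark(lm_point(lm2, nm), t_s, vs,
                                                  dims))
  list(volume = v2, landmarks = lm2,
       transforms = list(horizontal = t_h, sagittal = t_s))
}
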