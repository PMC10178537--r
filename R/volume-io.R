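#' MicroCT volume container
#'
#' A `volume` is a 3D grayscale intensity array with mandatory spatial
#' metadata. The axis order is fixed and anatomical: the first array
#' dimension is dorsoventral (x, index 1 = dorsal-most), the second
#' mediolateral (y) and the third anteroposterior (z). Voxels are isotropic.
#' Voxel indices are 1-based; the physical position of index `i` along any
#' axis is `(i - 1) * voxel_size` micrometres.
#'
#' @param data 3D numeric/integer array of intensities.
#' @param voxel_size isotropic voxel edge length in micrometres (> 0).
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return An object of class `volume`.
#' @export
volume <- function(data, voxel_size, bit_depth = 16L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (um)")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  rng <- range(data, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("intensities outside the declared bit range")
  structure(
    data,
    voxel_size = voxel_size,
    bit_depth = as.integer(bit_depth),
    axes = c("dorsoventral", "mediolateral", "anteroposterior"),
    class = c("volume", "array")
  )
}

# internal constructor for data already known to be in range (skips the
# full-array validation scan, which matters at tens of millions of voxels)
new_volume <- function(data, voxel_size, bit_depth) {
  structure(data, voxel_size = voxel_size, bit_depth = as.integer(bit_depth),
            axes = c("dorsoventral", "mediolateral", "anteroposterior"),
            class = c("volume", "array"))
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<volume> %d x %d x %d voxels (%s), %.4g um/voxel, %d-bit\n",
    d[1], d[2], d[3], paste(attr(x, "axes"), collapse = " x "),
    attr(x, "voxel_size"), attr(x, "bit_depth")))
  invisible(x)
}

voxel_size <- function(v) attr(v, "voxel_size")
bit_depth <- function(v) attr(v, "bit_depth")

# Operations refuse arrays that lost their axis metadata.
assert_volume <- function(v) {
  if (!inherits(v, "volume") || is.null(attr(v, "axes")) ||
      is.null(attr(v, "voxel_size")))
    stop("not a `volume` (axis metadata is mandatory)")
  invisible(v)
}

#' Convert a 16-bit volume to 8-bit
#'
#' Linear min-max rescaling of the observed intensity range onto
#' `[0, 255]`, with half-up rounding, mirroring the preprocessing applied
#' to scanner output before morphometry. The rescale window is per-volume.
#'
#' @param v a 16-bit [volume].
#' @return An 8-bit [volume] with the same dimensions and voxel size.
#' @export
convert_to_8bit <- function(v) {
  assert_volume(v)
  if (bit_depth(v) != 16L) stop("`v` must be 16-bit")
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warning("constant volume: contrast undefined, mapping to all zeros")
    out <- array(0L, dim(v))
  } else {
    x <- unclass(v)
    if (!is.integer(x)) x <- array(as.integer(round(x)), dim(x))
    out <- .rescale_8bit_cpp(x, lo, hi)
  }
  new_volume(out, voxel_size(v), 8L)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(v, path) {
  meta <- list(voxel_size = voxel_size(v), bit_depth = bit_depth(v),
               axes = attr(v, "axes"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

guess_format <- function(path) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) "tiff_stack"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else stop("cannot infer volume format from extension: ", path)
}

#' Write a volume to disk
#'
#' TIFF stacks are written one page per dorsoventral (x) slice; NIfTI-1
#' files carry the voxel size in their pixdim. Both formats get a JSON
#' sidecar (`<path>.json`) holding voxel size, bit depth and axis order,
#' which [read_volume()] uses to restore metadata exactly.
#'
#' @param v a [volume].
#' @param path output file (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @param format `"tiff_stack"` or `"nifti"`; inferred from the extension
#'   by default.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, format = guess_format(path)) {
  assert_volume(v)
  format <- match.arg(format, c("tiff_stack", "nifti"))
  if (format == "tiff_stack") {
    maxval <- 2^bit_depth(v) - 1
    pages <- lapply(seq_len(dim(v)[1]),
                    function(i) v[i, , , drop = TRUE] / maxval)
    tiff::writeTIFF(pages, path, bits.per.sample = bit_depth(v))
  } else {
    img <- RNifti::asNifti(array(as.integer(v), dim(v)))
    RNifti::pixdim(img) <- rep(voxel_size(v) / 1000, 3) # NIfTI pixdim in mm
    RNifti::writeNifti(img, path)
  }
  write_sidecar(v, path)
  invisible(path)
}

#' Read a volume from disk
#'
#' Restores the [volume] written by [write_volume()]. Metadata comes from
#' the JSON sidecar when present; otherwise `voxel_size` must be supplied
#' (TIFF) or is taken from the NIfTI pixdim. Anisotropic NIfTI voxels are
#' rejected: the pipeline assumes a single isotropic voxel size.
#'
#' @param path file written by [write_volume()].
#' @param format `"tiff_stack"` or `"nifti"`; inferred by default.
#' @param voxel_size fallback voxel size in um when no sidecar exists.
#' @return A [volume].
#' @export
read_volume <- function(path, format = guess_format(path),
                        voxel_size = NULL) {
  format <- match.arg(format, c("tiff_stack", "nifti"))
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0L, c(length(pages), dim(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    vs <- meta$voxel_size %||% voxel_size
    if (is.null(vs)) stop("TIFF carries no voxel size: supply `voxel_size` ",
                          "or keep the JSON sidecar")
    bd <- meta$bit_depth %||% if (max(arr) > 255) 16L else 8L
    volume(arr, as.numeric(vs), as.integer(bd))
  } else {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3] * 1000
    if (diff(range(pd)) > 1e-3 * mean(pd))
      stop("anisotropic voxels (", paste(signif(pd, 6), collapse = " x "),
           " um): the pipeline assumes isotropic voxels")
    vs <- meta$voxel_size %||% mean(pd)
    bd <- meta$bit_depth %||% if (max(img) > 255) 16L else 8L
    volume(array(as.integer(img), dim(img)[1:3]), as.numeric(vs),
           as.integer(bd))
  }
}

#' Landmark sets
#'
#' Named anatomical points of one skull in 1-based voxel coordinates
#' (fractional values allowed). Recognised names are `bregma`, `lambda`,
#' `parietal_edge_left` and `parietal_edge_right`; bregma and lambda are
#' required by the alignment and slicing stages.
#'
#' @param skull_id identifier of the scan.
#' @param points named list (or 3-column matrix with rownames) of
#'   `c(x, y, z)` voxel coordinates.
#' @return A `landmark_set`: a data frame with columns
#'   `skull_id, name, x, y, z`.
#' @export
landmark_set <- function(skull_id, points) {
  if (is.matrix(points)) {
    nm <- rownames(points)
    points <- lapply(seq_len(nrow(points)), function(i) points[i, ])
    names(points) <- nm
  }
  if (is.null(names(points)) || any(names(points) == ""))
    stop("landmark points must be named")
  df <- data.frame(
    skull_id = skull_id,
    name = names(points),
    do.call(rbind, lapply(points, function(p) {
      stopifnot(length(p) == 3)
      data.frame(x = p[1], y = p[2], z = p[3])
    })),
    row.names = NULL
  )
  if (all(c("bregma", "lambda") %in% df$name)) {
    b <- lm_point(df, "bregma"); l <- lm_point(df, "lambda")
    if (all(abs(b - l) < 1e-9)) stop("bregma and lambda coincide")
  }
  class(df) <- c("landmark_set", "data.frame")
  df
}

#' Extract one landmark as a coordinate vector
#' @param lm a [landmark_set].
#' @param name landmark name.
#' @return Numeric `c(x, y, z)` in 1-based voxel coordinates.
#' @export
lm_point <- function(lm, name) {
  i <- match(name, lm$name)
  if (is.na(i)) stop("landmark not present: ", name)
  unlist(lm[i, c("x", "y", "z")], use.names = FALSE)
}

lm_replace <- function(lm, name, p) {
  i <- match(name, lm$name)
  lm[i, c("x", "y", "z")] <- as.list(p)
  lm
}

#' Read/write landmark tables
#'
#' CSV with columns `skull_id,name,x,y,z`. Coordinates are 1-based voxel
#' indices (a header comment in the file records this convention).
#'
#' @param lm a [landmark_set].
#' @param path CSV file.
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a [landmark_set] (or a list of them when the file holds
#'   several skulls).
#' @export
write_landmarks <- function(lm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(
    "# landmark voxel coordinates, 1-based;",
    "physical position (um) = (index - 1) * voxel_size"), con)
  utils::write.csv(as.data.frame(lm), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("skull_id", "name", "x", "y", "z")
  if (!all(need %in% names(df))) stop("landmark CSV must have columns ",
                                      paste(need, collapse = ","))
  split_df <- split(df, df$skull_id)
  sets <- lapply(split_df, function(d) {
    pts <- lapply(seq_len(nrow(d)), function(i) unlist(d[i, c("x", "y", "z")]))
    names(pts) <- d$name
    landmark_set(d$skull_id[1], pts)
  })
  if (length(sets) == 1L) sets[[1]] else sets
}
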