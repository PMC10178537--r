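# Synthetic polarized Raman line maps with known ground truth.

#' Ground truth for synthetic bone Raman spectra
#'
#' Describes spectra as a sum of pseudo-Voigt bands plus a linear baseline
#' and additive Gaussian noise on a regular wavenumber grid. Defaults
#' mirror a polarized (zz) acquisition of mouse calvarial bone over the
#' 760-1020 cm^-1 region sampled every 0.5 cm^-1, with the
#' [default_bone_bands()] as generating bands.
#'
#' @param peaks generating band table (`assignment, center, height, fwhm,
#'   eta`).
#' @param baseline `c(intercept, slope)` of the linear background.
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param grid `c(from, to, step)` wavenumber grid in cm^-1.
#' @param seed RNG seed.
#' @return A validated `raman_truth` list.
#' @export
raman_truth <- function(peaks = default_bone_bands(),
                        baseline = c(intercept = 60, slope = 0.05),
                        noise_sd = 0, grid = c(760, 1020, 0.5),
                        seed = 1L) {
  if (any(peaks$center < grid[1] | peaks$center > grid[2]))
    stop("peak centers must lie inside the grid range")
  if (any(peaks$height <= 0)) stop("peak heights must be positive")
  if (any(peaks$fwhm <= 0)) stop("peak widths must be positive")
  if (any(peaks$eta < 0 | peaks$eta > 1))
    stop("gaussian fractions must lie in [0, 1]")
  structure(list(peaks = peaks, baseline = baseline, noise_sd = noise_sd,
                 grid = grid, seed = as.integer(seed)),
            class = "raman_truth")
}

# Noise-free model spectrum for a truth object, with the nu1 phosphate
# height scaled by `po4_scale`.
truth_model <- function(truth, wn, po4_scale = 1) {
  y <- truth$baseline[[1]] + truth$baseline[[2]] * wn
  for (i in seq_len(nrow(truth$peaks))) {
    p <- truth$peaks[i, ]
    h <- if (identical(p$assignment, "nu1_PO4")) p$height * po4_scale
    else p$height
    y <- y + pseudo_voigt(wn, p$center, h, p$fwhm, p$eta)
  }
  y
}

#' Suture dip profile for a synthetic line map
#'
#' Per-point scaling of the nu1 phosphate band along a line map crossing a
#' suture: 1 on the mineralised plateau, dipping by `depth` at the suture
#' centre with a Gaussian lateral profile.
#'
#' @param n number of map points.
#' @param depth fractional dip of the phosphate band at the centre
#'   (0.5 = halved).
#' @param center dip position (index units; defaults to the map midpoint).
#' @param width Gaussian sigma of the dip in index units.
#' @return Numeric vector of length `n` in `(0, 1]`.
#' @export
suture_dip_profile <- function(n, depth = 0.5, center = (n + 1) / 2,
                               width = n / 10) {
  i <- seq_len(n)
  1 - depth * exp(-((i - center) / width)^2 / 2)
}

#' Generate a synthetic Raman line map
#'
#' Produces `n_points` spectra spaced `spacing` micrometres apart, emulating
#' a polarized line scan across a calvarial suture: the nu1 phosphate band
#' height follows `suture_profile`, so the I961/I1005 ratio dips where the
#' profile does, while matrix bands and baseline stay constant. Noise is
#' independent Gaussian per point, deterministic given the truth seed.
#'
#' @param truth a [raman_truth].
#' @param n_points number of spectra (>= 1); the protocol used ~30.
#' @param suture_profile per-point scaling of the phosphate band (length
#'   `n_points`); default flat (no suture).
#' @param spacing distance between points, um.
#' @return List of [raman_spectrum] objects with attributes
#'   `truth_min_index` (index set of the generating profile minimum) and
#'   `truth` attached.
#' @export
make_raman_linemap <- function(truth, n_points = 30L, suture_profile = NULL,
                               spacing = 10) {
  stopifnot(inherits(truth, "raman_truth"), n_points >= 1)
  profile <- suture_profile %||% rep(1, n_points)
  if (length(profile) != n_points)
    stop("`suture_profile` must have length `n_points`")
  wn <- seq(truth$grid[1], truth$grid[2], by = truth$grid[3])
  noise <- if (truth$noise_sd > 0)
    with_seed(truth$seed,
              matrix(stats::rnorm(length(wn) * n_points, sd = truth$noise_sd),
                     length(wn), n_points))
  else matrix(0, length(wn), n_points)
  spectra <- lapply(seq_len(n_points), function(i) {
    raman_spectrum(wn, truth_model(truth, wn, profile[i]) + noise[, i],
                   position = (i - 1) * spacing)
  })
  structure(spectra,
            truth_min_index = which(profile <= min(profile) * (1 + 1e-12)),
            truth = truth, profile = profile)
}

#' Write a line map to disk
#'
#' One two-column CSV per point plus a manifest CSV (`index, position_um,
#' file`).
#'
#' @param map list of [raman_spectrum] objects.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Path of the manifest, invisibly.
#' @export
write_linemap <- function(map, dir, prefix = "point") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(map))
  for (i in seq_along(map)) {
    files[i] <- file.path(dir, sprintf("%s_%03d.csv", prefix, i))
    write_spectrum(map[[i]], files[i])
  }
  manifest <- data.frame(
    index = seq_along(map),
    position_um = vapply(map, function(s) attr(s, "position"), numeric(1)),
    file = basename(files))
  mpath <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @rdname write_linemap
#' @param manifest path to a manifest CSV written by [write_linemap()].
#' @export
read_linemap <- function(manifest) {
  man <- utils::read.csv(manifest)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    read_spectrum(file.path(dir, man$file[i]), position = man$position_um[i])
  })
}
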