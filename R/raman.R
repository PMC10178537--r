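# Polarized Raman metrology of bone: pseudo-Voigt band decomposition,
# mineral-to-matrix ratios and crystallinity.

#' Pseudo-Voigt line profile
#'
#' Weighted mix of a Gaussian and a Lorentzian sharing centre, height and
#' FWHM: `eta * G + (1 - eta) * L` with `eta` the Gaussian fraction. The
#' value at the centre equals `height` for every `eta`, and the value at
#' `center +/- fwhm/2` equals `height / 2` (both component profiles share
#' their full width at half maximum).
#'
#' @param x wavenumbers (cm^-1).
#' @param center band centre (cm^-1).
#' @param height peak height at the centre.
#' @param fwhm full width at half maximum (cm^-1, > 0).
#' @param eta Gaussian fraction in `[0, 1]`.
#' @return Profile values at `x`.
#' @export
pseudo_voigt <- function(x, center, height, fwhm, eta) {
  u <- (x - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  height * (eta * g + (1 - eta) * l)
}

#' Closed-form area under a pseudo-Voigt band
#' @inheritParams pseudo_voigt
#' @return Integrated area, `height * fwhm * (eta * sqrt(pi / log(2)) / 2 +
#'   (1 - eta) * pi / 2)`.
#' @export
pseudo_voigt_area <- function(height, fwhm, eta) {
  height * fwhm * (eta * 0.5 * sqrt(pi / log(2)) + (1 - eta) * pi / 2)
}

#' Default bone Raman band table
#'
#' Literature-typical positions of eight bands of mineralised tissue in the
#' 830-1020 cm^-1 fingerprint window: tyrosine, proline (855),
#' hydroxyproline (876), two C-C backbone modes, the nu1 phosphate stretch
#' (961, bone mineral) and phenylalanine (1005, collagen matrix). These are
#' package defaults intended as fit seeds and as the synthetic generating
#' truth; any instrument-specific table can be supplied instead.
#'
#' @return Data frame with columns `assignment`, `center`, `height`,
#'   `fwhm`, `eta`.
#' @export
default_bone_bands <- function() {
  data.frame(
    assignment = c("Tyr", "Pro", "Hyp", "nu_CC", "Pro_ring", "CC_backbone",
                   "nu1_PO4", "Phe"),
    center = c(836, 855, 876, 898, 921, 940, 961, 1005),
    height = c(220, 320, 300, 200, 280, 300, 1000, 400),
    fwhm = c(12, 13, 13, 16, 14, 18, 11.5, 8),
    eta = c(0.5, 0.6, 0.6, 0.5, 0.5, 0.5, 0.7, 0.8)
  )
}

#' Read/write a band table as JSON
#'
#' Band configurations (assignment, seed centre, and optionally height,
#' fwhm, eta initial values) can be shipped alongside a study and loaded
#' at fit time, so instrument-specific tables replace the package default.
#'
#' @param bands a band table as in [default_bone_bands()].
#' @param path JSON file.
#' @return `read_band_config` returns the band table data frame.
#' @export
write_band_config <- function(bands, path) {
  jsonlite::write_json(bands, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_band_config
#' @export
read_band_config <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("assignment", "center") %in% names(df)))
    stop("band config must contain at least `assignment` and `center`")
  as.data.frame(df)
}

#' A single Raman spectrum
#' @param wavenumbers strictly increasing grid (cm^-1).
#' @param intensities counts, same length.
#' @param position position along the line map (um).
#' @param polarization acquisition label (carried, not modelled).
#' @return A `raman_spectrum` data frame.
#' @export
raman_spectrum <- function(wavenumbers, intensities, position = NA_real_,
                           polarization = "zz") {
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumber grid must be strictly increasing")
  if (length(intensities) != length(wavenumbers) || !all(is.finite(intensities)))
    stop("intensities must be finite and match the grid")
  structure(data.frame(wavenumber = wavenumbers, intensity = intensities),
            position = position, polarization = polarization,
            class = c("raman_spectrum", "data.frame"))
}

#' Decompose a bone Raman spectrum into pseudo-Voigt bands
#'
#' Nonlinear least squares of a sum of pseudo-Voigt profiles plus a linear
#' baseline over the fitting window (default 830-1020 cm^-1, the bone
#' fingerprint region). Band centres are bounded within +/-10 cm^-1 of
#' their seeds, Gaussian fractions within `[0, 1]` and widths within
#' (0, 60] cm^-1. The optimisation (Levenberg-Marquardt) is deterministic
#' for identical seeds and data.
#'
#' @param s a [raman_spectrum].
#' @param bands seed table as in [default_bone_bands()]; `height`, `fwhm`
#'   and `eta` columns, when present, initialise the optimiser.
#' @param window fitting window `c(lo, hi)` in cm^-1.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return A `raman_fit` data frame (`assignment`, `center`, `height`,
#'   `fwhm`, `eta`, `area`) with attributes `baseline`
#'   (`c(intercept, slope)`), `rms_residual` and `window`.
#' @export
fit_raman_peaks <- function(s, bands = default_bone_bands(),
                            window = c(830, 1020), max_iter = 200L) {
  stopifnot(inherits(s, "raman_spectrum"))
  wn <- s$wavenumber
  if (window[1] < min(wn) || window[2] > max(wn))
    stop("fitting window not covered by the spectrum grid")
  if (nrow(bands) < 1) stop("at least one seed band is required")
  if (any(bands$center < window[1] | bands$center > window[2]))
    stop("seed centers must lie inside the fitting window")
  cs <- sort(bands$center)
  if (length(cs) > 1 && min(diff(cs)) < 2)
    stop("overlapping seeds: band centers closer than 2 cm^-1")
  sel <- wn >= window[1] & wn <= window[2]
  x <- wn[sel]; y <- s$intensity[sel]

  nb <- nrow(bands)
  y1 <- stats::median(utils::head(y, 5)); y2 <- stats::median(utils::tail(y, 5))
  x1 <- x[3]; x2 <- x[length(x) - 2]
  b_slope <- (y2 - y1) / (x2 - x1)
  base_init <- c(y1 - b_slope * x1, b_slope)
  h_init <- bands$height %||% NULL
  if (is.null(h_init))
    h_init <- vapply(bands$center, function(c0) {
      max(y[which.min(abs(x - c0))] - (base_init[1] + base_init[2] * c0), 1)
    }, numeric(1))
  par <- c(rbind(bands$center,
                 pmax(h_init, 1),
                 bands$fwhm %||% rep(12, nb),
                 bands$eta %||% rep(0.5, nb)),
           base_init[1], base_init[2])
  lower <- c(rbind(pmax(bands$center - 10, window[1]),
                   rep(0, nb), rep(0.5, nb), rep(0, nb)), -Inf, -Inf)
  upper <- c(rbind(pmin(bands$center + 10, window[2]),
                   rep(3 * max(y), nb), rep(60, nb), rep(1, nb)), Inf, Inf)

  model <- function(p) {
    m <- p[4 * nb + 1] + p[4 * nb + 2] * x
    for (i in seq_len(nb)) {
      o <- 4 * (i - 1)
      m <- m + pseudo_voigt(x, p[o + 1], p[o + 2], p[o + 3], p[o + 4])
    }
    m
  }
  # analytic Jacobian: the 34-parameter problem is ill-conditioned (strong
  # height/width/shape correlations between overlapping bands), and
  # finite-difference steps stall in its flat valleys
  jac <- function(p) {
    J <- matrix(0, length(x), length(p))
    for (i in seq_len(nb)) {
      o <- 4 * (i - 1)
      cc <- p[o + 1]; h <- p[o + 2]; w <- p[o + 3]; eta <- p[o + 4]
      u <- (x - cc) / w
      g <- exp(-4 * log(2) * u^2)
      l <- 1 / (1 + 4 * u^2)
      shape <- eta * g + (1 - eta) * l
      dshape_du <- eta * (-8 * log(2) * u * g) + (1 - eta) * (-8 * u * l^2)
      J[, o + 1] <- h * dshape_du * (-1 / w) # d/dc via du/dc = -1/w
      J[, o + 2] <- shape
      J[, o + 3] <- h * dshape_du * (-u / w)
      J[, o + 4] <- h * (g - l)
    }
    J[, 4 * nb + 1] <- 1
    J[, 4 * nb + 2] <- x
    J
  }
  fit <- minpack.lm::nls.lm(par, lower, upper,
                            fn = function(p) model(p) - y,
                            jac = jac,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ptol = 1e-14, ftol = 1e-14))
  rms <- sqrt(mean(fit$fvec^2))
  if (fit$info == 0 || fit$info == 5)
    stop(sprintf("peak fit did not converge (info %d, last rms residual %.4g)",
                 fit$info, rms))
  p <- fit$par
  idx <- seq_len(nb)
  out <- data.frame(
    assignment = bands$assignment %||% paste0("band", idx),
    center = p[4 * (idx - 1) + 1],
    height = p[4 * (idx - 1) + 2],
    fwhm = p[4 * (idx - 1) + 3],
    eta = p[4 * (idx - 1) + 4])
  out$area <- pseudo_voigt_area(out$height, out$fwhm, out$eta)
  structure(out,
            baseline = c(intercept = unname(p[4 * nb + 1]),
                         slope = unname(p[4 * nb + 2])),
            rms_residual = rms, window = window, info = fit$info,
            class = c("raman_fit", "data.frame"))
}

#' Mineral-to-matrix ratios and crystallinity from fitted bands
#'
#' Ratios of the nu1 phosphate band (961 cm^-1) to the matrix bands:
#' I961/I1005 (phenylalanine), and when present I961/I_Pro and I961/I_Hyp.
#' Intensities are fitted heights by default (matching the I-notation);
#' integrated areas are available as an option. Crystallinity is the
#' inverse FWHM of the nu1 phosphate band (narrower band = more ordered
#' mineral), in cm.
#'
#' @param peaks a `raman_fit` (or compatible data frame with `assignment`,
#'   `height`, `area`, `fwhm` columns).
#' @param use `"height"` or `"area"`.
#' @return A `ratio_set`: list with `ratios` (named numeric) and
#'   `crystallinity`.
#' @export
compute_band_ratios <- function(peaks, use = c("height", "area")) {
  use <- match.arg(use)
  get <- function(lab) {
    i <- match(lab, peaks$assignment)
    if (is.na(i)) return(NULL)
    peaks[i, ]
  }
  po4 <- get("nu1_PO4"); phe <- get("Phe")
  if (is.null(po4) || is.null(phe))
    stop("assignments nu1_PO4 and Phe are required")
  val <- function(row) row[[use]]
  ratios <- c(PO4_Phe = val(po4) / val(phe))
  pro <- get("Pro"); hyp <- get("Hyp")
  if (!is.null(pro)) ratios <- c(ratios, PO4_Pro = val(po4) / val(pro))
  if (!is.null(hyp)) ratios <- c(ratios, PO4_Hyp = val(po4) / val(hyp))
  structure(list(ratios = ratios, crystallinity = 1 / po4$fwhm,
                 intensity_measure = use),
            class = "ratio_set")
}

#' Select the spectra that represent the suture region
#'
#' In a line map crossing a suture, the unossified gap has the lowest
#' mineral-to-matrix ratio; the spectra attaining the minimal I961/I1005
#' (within a relative tie tolerance) are taken to represent the suture.
#'
#' @param ratios numeric vector of I961/I1005 per map point (`NA` for
#'   failed fits).
#' @param tol relative tie tolerance (default 1%).
#' @return Integer indices of the selected spectra.
#' @export
select_suture_spectra <- function(ratios, tol = 0.01) {
  ok <- which(is.finite(ratios))
  if (length(ok) == 0) stop("all fits failed: no ratios to select from")
  if (length(ok) < 3)
    stop("at least 3 successfully fitted spectra are required")
  m <- min(ratios[ok])
  ok[ratios[ok] <= m * (1 + tol)]
}

#' Summarise ratio metrology over the line maps of one specimen
#'
#' Fits every spectrum of every line map, selects the suture-region spectra
#' of each map by minimal I961/I1005, and pools the selected spectra's
#' ratio-set entries into a mean +/- sd per metric.
#'
#' @param maps list of line maps; each line map is a list of
#'   [raman_spectrum] objects (as produced by [make_raman_linemap()]).
#' @param bands,window,use passed to [fit_raman_peaks()] /
#'   [compute_band_ratios()].
#' @return Data frame `metric, mean, sd, n` (sd is `NA` for n = 1).
#' @export
summarize_linemaps <- function(maps, bands = default_bone_bands(),
                               window = c(830, 1020), use = "height") {
  if (!length(maps)) stop("at least one line map is required")
  vals <- list()
  for (map in maps) {
    fits <- lapply(map, function(sp) {
      tryCatch(fit_raman_peaks(sp, bands, window), error = function(e) NULL)
    })
    ratios <- vapply(fits, function(f) {
      if (is.null(f)) return(NA_real_)
      compute_band_ratios(f, use)$ratios[["PO4_Phe"]]
    }, numeric(1))
    sel <- select_suture_spectra(ratios)
    for (i in sel) {
      rs <- compute_band_ratios(fits[[i]], use)
      vals[[length(vals) + 1L]] <- c(rs$ratios,
                                     crystallinity = rs$crystallinity)
    }
  }
  m <- do.call(rbind, vals)
  data.frame(metric = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, function(z) if (length(z) > 1) stats::sd(z)
                        else NA_real_),
             n = nrow(m), row.names = NULL)
}

#' Read/write two-column spectrum files
#'
#' Plain CSV with columns `wavenumber_cm-1,intensity`, one file per map
#' point, plus a manifest CSV (`index,position_um,file`) tying a line map
#' together.
#'
#' @param s a [raman_spectrum]; `path` a CSV file.
#' @return `read_spectrum` returns a [raman_spectrum].
#' @export
write_spectrum <- function(s, path) {
  df <- data.frame(`wavenumber_cm-1` = s$wavenumber, intensity = s$intensity,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @param path CSV file.
#' @param position,polarization metadata for the restored spectrum.
#' @export
read_spectrum <- function(path, position = NA_real_, polarization = "zz") {
  df <- utils::read.csv(path, check.names = FALSE)
  raman_spectrum(df[[1]], df[[2]], position, polarization)
}
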