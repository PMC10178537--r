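bb <- default_bone_bands()

test_that("the pseudo-Voigt profile honours its height and FWHM definition", {
  for (eta in seq(0, 1, by = 0.25)) {
    expect_equal(pseudo_voigt(961, 961, 123, 10, eta), 123)
    expect_equal(pseudo_voigt(961 + 5, 961, 123, 10, eta), 123 / 2)
    expect_equal(pseudo_voigt(961 - 5, 961, 123, 10, eta), 123 / 2)
  }
  # closed-form area against numerical integration
  x <- seq(950 - 4000, 950 + 4000, by = 0.02)
  for (eta in c(0, 0.4, 1)) {
    num <- sum(pseudo_voigt(x, 950, 80, 12, eta)) * 0.02
    tol <- if (eta == 1) 1e-6 else 2e-3 # Lorentzian tails converge slowly
    expect_equal(pseudo_voigt_area(80, 12, eta), num, tolerance = tol)
  }
})

test_that("a noiseless single band is recovered to machine-level precision", {
  wn <- seq(760, 1020, 0.5)
  s <- raman_spectrum(wn, 20 + 0.03 * wn + pseudo_voigt(wn, 961, 500, 12, 1))
  f <- fit_raman_peaks(s, data.frame(assignment = "nu1_PO4", center = 958,
                                     height = 300, fwhm = 16, eta = 0.4))
  expect_equal(f$center, 961, tolerance = 1e-7)
  expect_equal(f$height, 500, tolerance = 1e-6)
  expect_equal(f$fwhm, 12, tolerance = 1e-6)
  expect_equal(f$eta, 1, tolerance = 1e-4)
  expect_equal(attr(f, "baseline")[["intercept"]], 20, tolerance = 1e-4)
})

test_that("the nonlinear fit agrees with brute-force grid search on a noiseless peak", {
  wn <- seq(830, 1020, 0.5)
  truth <- c(center = 940, height = 300, fwhm = 14)
  s <- raman_spectrum(wn, 50 + pseudo_voigt(wn, truth["center"],
                                            truth["height"], truth["fwhm"],
                                            0.5))
  f <- fit_raman_peaks(s, data.frame(assignment = "x", center = 942,
                                     height = 250, fwhm = 10, eta = 0.5))
  gs <- peak_grid_search(wn, s$intensity, 50, 940, 300, 14, eta = 0.5)
  expect_lt(abs(f$center - gs$par[1]), gs$resolution[1])
  expect_lt(abs(f$height - gs$par[2]), gs$resolution[2])
  expect_lt(abs(f$fwhm - gs$par[3]), gs$resolution[3])
})

test_that("fit preconditions and failure modes are enforced", {
  wn <- seq(760, 1020, 1)
  s <- raman_spectrum(wn, 100 + pseudo_voigt(wn, 961, 500, 12, 0.7))
  expect_error(fit_raman_peaks(s, data.frame(center = c(960, 961.5))),
               "closer than 2")
  expect_error(fit_raman_peaks(s, data.frame(center = 700)),
               "inside the fitting window")
  expect_error(fit_raman_peaks(s, bb, window = c(700, 1020)),
               "not covered")
  expect_error(raman_spectrum(c(1, 1, 2), c(0, 0, 0)),
               "strictly increasing")
})

test_that("eight-band recovery at the calibrated noise envelope", {
  # Envelope calibrated over 20 noise seeds at worst-band SNR 50 and then
  # frozen: centers within 0.5 cm^-1 (max), per-band mean |height error|
  # within 5% (the Cramer-Rao bound of this model puts the worst band near
  # 4%, so a tighter envelope is not attainable at this SNR).
  errs <- sapply(1:20, function(s) {
    tr <- raman_truth(noise_sd = min(bb$height) / 50, seed = s)
    m <- make_raman_linemap(tr, n_points = 1)
    f <- fit_raman_peaks(m[[1]], bb)
    c(max(abs(f$center - bb$center)), abs(f$height / bb$height - 1))
  })
  expect_lt(max(errs[1, ]), 0.5)
  expect_lt(max(rowMeans(errs[-1, , drop = FALSE])), 0.05)
})

test_that("ratios and crystallinity follow their definitions and scale invariance", {
  pk <- data.frame(assignment = c("nu1_PO4", "Phe"),
                   center = c(961, 1005), height = c(100, 50),
                   fwhm = c(16, 9), eta = c(0.5, 0.5),
                   area = pseudo_voigt_area(c(100, 50), c(16, 9), 0.5))
  rs <- compute_band_ratios(pk)
  expect_equal(unname(rs$ratios["PO4_Phe"]), 2)
  expect_equal(rs$crystallinity, 1 / 16)
  expect_error(compute_band_ratios(pk[1, ]), "required")

  # multiplying the whole spectrum by a constant cancels in every ratio
  tr <- raman_truth(noise_sd = 0)
  sp <- make_raman_linemap(tr, n_points = 1)[[1]]
  f1 <- compute_band_ratios(fit_raman_peaks(sp, bb))
  sp4 <- raman_spectrum(sp$wavenumber, 4 * sp$intensity)
  f4 <- compute_band_ratios(fit_raman_peaks(sp4, bb))
  expect_equal(f4$ratios, f1$ratios, tolerance = 1e-6)
  expect_equal(f4$crystallinity, f1$crystallinity, tolerance = 1e-6)
})

test_that("suture selection finds minimal-ratio spectra with ties and idempotence", {
  expect_equal(select_suture_spectra(c(5, 4, 3, 2, 1)), 5L)
  expect_equal(select_suture_spectra(c(3, 2, 1, 1, 2, 3)), c(3L, 4L))
  expect_error(select_suture_spectra(c(NA, NA, 1, 2)), "at least 3")
  sel <- select_suture_spectra(c(2, 1.004, 1, 1.5, 3))
  expect_equal(sel, c(2L, 3L))
  # idempotence: re-selecting among the selected returns all of them
  r <- c(2, 1.004, 1, 1.5, 3, 1.002)
  sel1 <- select_suture_spectra(r)
  expect_equal(select_suture_spectra(r[sel1]), seq_along(sel1))
})

test_that("the generating dip index is recovered from a fitted line map", {
  tr <- raman_truth(noise_sd = min(bb$height) / 50, seed = 12)
  prof <- suture_dip_profile(9, depth = 0.5)
  map <- make_raman_linemap(tr, n_points = 9, suture_profile = prof)
  ratios <- vapply(map, function(sp)
    compute_band_ratios(fit_raman_peaks(sp, bb))$ratios[["PO4_Phe"]],
    numeric(1))
  expect_true(all(select_suture_spectra(ratios) %in%
                    attr(map, "truth_min_index")))
  # exhaustive oracle: the fitted minimum is the generating minimum
  expect_equal(which.min(ratios), 5L)
})

test_that("line-map summaries pool the selected spectra correctly", {
  tr <- raman_truth(noise_sd = 0)
  map <- make_raman_linemap(tr, n_points = 5,
                            suture_profile = suture_dip_profile(5, 0.4))
  one <- summarize_linemaps(list(map), bb)
  expect_true(all(c("PO4_Phe", "crystallinity") %in% one$metric))
  # identical maps: pooled sd over selected spectra is 0
  two <- summarize_linemaps(list(map, map), bb)
  expect_equal(two$sd, rep(0, nrow(two)), tolerance = 1e-8)
  expect_equal(two$mean, one$mean, tolerance = 1e-8)

  # crystallinity separates groups generated with different nu1 widths
  bb_wide <- bb; bb_wide$fwhm[bb_wide$assignment == "nu1_PO4"] <- 16
  map_wide <- make_raman_linemap(raman_truth(peaks = bb_wide, noise_sd = 0),
                                 n_points = 5,
                                 suture_profile = suture_dip_profile(5, 0.4))
  s_narrow <- summarize_linemaps(list(map), bb)
  s_wide <- summarize_linemaps(list(map_wide), bb)
  cn <- function(s) s$mean[s$metric == "crystallinity"]
  expect_gt(cn(s_narrow), cn(s_wide))
  expect_equal(cn(s_narrow), 1 / 11.5, tolerance = 1e-3)
  expect_equal(cn(s_wide), 1 / 16, tolerance = 1e-3)
})

test_that("band configurations round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  write_band_config(bb, f)
  expect_equal(read_band_config(f), bb)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(center = 1), bad)
  expect_error(read_band_config(bad), "assignment")
})

test_that("spectra and line maps round-trip through CSV files", {
  tr <- raman_truth(noise_sd = 100, seed = 2)
  map <- make_raman_linemap(tr, n_points = 3)
  d <- withr::local_tempdir()
  manifest <- write_linemap(map, d)
  back <- read_linemap(manifest)
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$intensity, map[[2]]$intensity, tolerance = 1e-8)
  expect_equal(attr(back[[3]], "position"), 20)
})
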