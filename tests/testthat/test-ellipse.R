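test_that("the outer surface of a phantom slice lies on the analytic ellipse", {
  sp <- small_phantom_spec()
  ph <- make_skull_phantom(sp)
  s <- extract_slice(ph$volume, lm_point(ph$landmarks, "bregma"),
                     lm_point(ph$landmarks, "lambda"))
  vs <- sp$voxel_size
  le <- lm_point(ph$landmarks, "parietal_edge_left")
  re <- lm_point(ph$landmarks, "parietal_edge_right")
  pc <- detect_outer_surface(s, (le[1:2] - 1) * vs, (re[1:2] - 1) * vs)
  # each point within one pixel of the true outer ellipse
  r2 <- ((pc$x - ph$truth$center[1]) / ph$truth$a)^2 +
    ((pc$y - ph$truth$center[2]) / ph$truth$b)^2
  dist_px <- abs(sqrt(r2) - 1) * min(ph$truth$a, ph$truth$b) / vs
  expect_lt(max(dist_px), 1)
  # point count equals the spanned columns minus the skipped ones
  n_cols <- floor((re[2] - 1) * vs / vs) - ceiling((le[2] - 1) * vs / vs) + 1
  expect_equal(nrow(pc) + attr(pc, "n_skipped"), n_cols)
})

test_that("an all-background slice yields an insufficient-surface error", {
  s <- structure(matrix(0, 30, 30), pixel_size = 10, bit_depth = 8L,
                 provenance = list(), class = c("slice2d", "matrix", "array"))
  expect_error(detect_outer_surface(s, c(0, 0), c(0, 250), threshold = 50),
               "insufficient surface")
})

test_that("exact point clouds are fitted to machine precision", {
  # circle: roundness is exactly 1
  f <- fit_axis_aligned_ellipse(make_ellipse_point_cloud(1000, 1000, n = 200))
  expect_equal(roundness(f), 1, tolerance = 1e-9)
  expect_equal(f$a, 1000, tolerance = 1e-9)

  # half-arc ellipse with offset centre
  pc <- make_ellipse_point_cloud(2, 3, center = c(1, -1), n = 120)
  f2 <- fit_axis_aligned_ellipse(pc)
  expect_equal(unname(f2$center), c(1, -1), tolerance = 1e-9)
  expect_equal(f2$a, 2, tolerance = 1e-9)
  expect_equal(f2$b, 3, tolerance = 1e-9)
  expect_equal(roundness(f2), 1.5, tolerance = 1e-9)
  expect_lt(f2$rms_residual, 1e-12)

  expect_error(fit_axis_aligned_ellipse(data.frame(x = 1:4, y = c(1, 2, 1, 2))),
               "at least 5")
  expect_error(fit_axis_aligned_ellipse(data.frame(x = 1:9, y = 2 * (1:9))),
               "degenerate conic")
})

test_that("the linear fit agrees with brute-force grid search of the same residual", {
  cases <- list(c(a = 2, b = 3, cx = 1, cy = -1),
                c(a = 5, b = 4, cx = -2, cy = 0.5))
  for (cs in cases) {
    pc <- make_ellipse_point_cloud(cs["a"], cs["b"], cs[c("cx", "cy")],
                                   n = 150)
    f <- fit_axis_aligned_ellipse(pc)
    gs <- ellipse_grid_search(pc$x, pc$y, cs[c("cx", "cy")], cs[["a"]],
                              cs[["b"]], span = 0.03, steps = 9)
    expect_lt(abs(f$center[1] - gs$par[1]), gs$resolution[1])
    expect_lt(abs(f$center[2] - gs$par[2]), gs$resolution[2])
    expect_lt(abs(f$a - gs$par[3]), gs$resolution[3])
    expect_lt(abs(f$b - gs$par[4]), gs$resolution[4])
  }
})

test_that("roundness is invariant to translation and scale but not rotation", {
  pc <- make_ellipse_point_cloud(2, 3, c(0.5, 2), n = 80, noise_sd = 0.02,
                                 seed = 3)
  base <- roundness(fit_axis_aligned_ellipse(pc))
  for (i in 1:20) {
    sh <- stats::runif(2, -50, 50)
    sc <- stats::runif(1, 0.1, 10)
    moved <- data.frame(x = sc * (pc$x + sh[1]), y = sc * (pc$y + sh[2]))
    expect_equal(roundness(fit_axis_aligned_ellipse(moved)), base,
                 tolerance = 1e-8)
  }
  # a 90-degree rotation swaps the axes: b/a -> a/b
  rot <- data.frame(x = -pc$y, y = pc$x)
  expect_equal(roundness(fit_axis_aligned_ellipse(rot)), 1 / base,
               tolerance = 1e-8)
})

test_that("fitted roundness is unbiased under coordinate noise", {
  a <- 2000; b <- 2600
  vals <- vapply(1:100, function(s) {
    pc <- make_ellipse_point_cloud(a, b, c(0, 0), arc = c(0, 2 * pi),
                                   n = 300, noise_sd = 0.02 * a, seed = s)
    roundness(fit_axis_aligned_ellipse(pc))
  }, numeric(1))
  expect_lt(abs(mean(vals) - b / a), 0.01 * b / a)
})

test_that("the end-to-end phantom pipeline recovers roundness", {
  sp <- small_phantom_spec(noise_sd = 400, seed = 9)
  ph <- make_skull_phantom(sp)
  f <- slice_and_fit(ph$volume, ph$landmarks)
  expect_equal(roundness(f), ph$truth$b_over_a, tolerance = 0.03)
})

test_that("fitted roundness converges to truth as voxels shrink", {
  errs <- vapply(c(60, 40, 25), function(vx) {
    sp <- small_phantom_spec(voxel_size = vx,
                             shell_thickness = max(90, 1.5 * vx))
    ph <- make_skull_phantom(sp)
    abs(roundness(slice_and_fit(ph$volume, ph$landmarks)) -
          ph$truth$b_over_a)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})
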