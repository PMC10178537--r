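# Independent oracles. These deliberately avoid the code paths they check.

# The algebraic ellipse objective expressed directly in (X0, Y0, a, b):
# sum of squared conic residuals under the A + B = 1 normalisation.
ellipse_algebraic_rss <- function(X0, Y0, a, b, x, y) {
  A <- b^2 / (a^2 + b^2)
  B <- a^2 / (a^2 + b^2)
  lam <- a^2 * b^2 / (a^2 + b^2)
  sum((A * (x - X0)^2 + B * (y - Y0)^2 - lam)^2)
}

# Exhaustive grid search over (X0, Y0, a, b) minimising the same residual
# the linear fit minimises. `spans` gives half-widths of the search box
# around `center0`; `steps` the number of grid points per axis.
ellipse_grid_search <- function(x, y, center0, a0, b0,
                                span = 0.05, steps = 11L) {
  gx <- seq(center0[1] - span * a0, center0[1] + span * a0, length.out = steps)
  gy <- seq(center0[2] - span * b0, center0[2] + span * b0, length.out = steps)
  ga <- seq(a0 * (1 - span), a0 * (1 + span), length.out = steps)
  gb <- seq(b0 * (1 - span), b0 * (1 + span), length.out = steps)
  best <- NULL; best_rss <- Inf
  for (X0 in gx) for (Y0 in gy) for (a in ga) for (b in gb) {
    rss <- ellipse_algebraic_rss(X0, Y0, a, b, x, y)
    if (rss < best_rss) { best_rss <- rss; best <- c(X0, Y0, a, b) }
  }
  list(par = best, rss = best_rss,
       resolution = c(diff(gx[1:2]), diff(gy[1:2]), diff(ga[1:2]),
                      diff(gb[1:2])))
}

# Brute-force grid search for a single pseudo-Voigt band on a noiseless
# spectrum (baseline assumed known), minimising the sum of squares.
peak_grid_search <- function(x, y, baseline, center0, height0, fwhm0,
                             eta, span = 0.1, steps = 15L) {
  gc_ <- seq(center0 * (1 - 0.01), center0 * (1 + 0.01), length.out = steps)
  gh <- seq(height0 * (1 - span), height0 * (1 + span), length.out = steps)
  gw <- seq(fwhm0 * (1 - span), fwhm0 * (1 + span), length.out = steps)
  best <- NULL; best_rss <- Inf
  yy <- y - baseline
  for (c0 in gc_) for (h in gh) for (w in gw) {
    rss <- sum((pseudo_voigt(x, c0, h, w, eta) - yy)^2)
    if (rss < best_rss) { best_rss <- rss; best <- c(c0, h, w) }
  }
  list(par = best,
       resolution = c(diff(gc_[1:2]), diff(gh[1:2]), diff(gw[1:2])))
}
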