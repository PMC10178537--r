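# Small, fast phantom used by unit tests (coarse voxels; the realistic
# 15 um scale is exercised in the acceptance tests).
small_phantom_spec <- function(...) {
  args <- list(...)
  defaults <- list(semi_axis_dv = 900, semi_axis_ml = 1350,
                   semi_axis_ap = 700, shell_thickness = 90,
                   voxel_size = 25, seed = 1L)
  do.call(phantom_spec, utils::modifyList(defaults, args))
}

# Analytic height (1-based x voxel index) of the outer shell surface at an
# integer column (j, k) of an identity-pose phantom: the oracle for the
# edge-detection height recovery.
phantom_analytic_height <- function(ph, j, k) {
  sp <- ph$spec
  vs <- sp$voxel_size
  b <- lm_point(ph$landmarks_true, "bregma")
  l <- lm_point(ph$landmarks_true, "lambda")
  center_y <- b[2]
  center_z <- (b[3] + l[3]) / 2
  center_x <- b[1] + sp$semi_axis_dv / vs *
    sqrt(1 - sp$landmark_frac^2)
  rad <- 1 - ((j - center_y) / (sp$semi_axis_ml / vs))^2 -
    ((k - center_z) / (sp$semi_axis_ap / vs))^2
  if (rad <= 0) return(NA_real_)
  center_x - sp$semi_axis_dv / vs * sqrt(rad)
}

# Truth-frame landmark residual (voxels) after alignment.
landmark_residuals <- function(aligned_lm, true_lm,
                               names = c("bregma", "lambda")) {
  vapply(names, function(nm) {
    max(abs(lm_point(aligned_lm, nm) - lm_point(true_lm, nm)))
  }, numeric(1))
}
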