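# calvaria

Quantitative skull-vault morphometry and bone Raman metrology for mouse
models of craniosynostosis (premature cranial suture fusion, as in
ERF-related craniosynostosis).

When a suture fuses early, the growing brain deforms the calvaria: its
coronal cross-section becomes rounder. This package implements a global
shape descriptor that quantifies that change from microCT, together with
the two companion measurements used to characterise the phenotype:

1. **Roundness descriptor (b/a).** Each skull is aligned to a reference by
   shape-preserving (similarity) transforms estimated from the bregma and
   lambda landmarks — first in the horizontal (y–z) plane, then, after the
   landmark heights are recovered by edge detection, in the sagittal (x–z)
   plane. A coronal slice is extracted perpendicular to the bregma–lambda
   line at ¼ of the distance from bregma, the outer calvarial surface is
   collected as a point cloud between the parietal lateral edges, and an
   axis-aligned ellipse

   ((X − X₀)/a)² + ((Y − Y₀)/b)² = 1

   is fitted by linear least squares (algebraic residual, A + B = 1
   normalisation). The descriptor is b/a, the mediolateral over
   dorsoventral semi-axis ratio: 1 for a circular cross-section, ≈1.5 for a
   normal mouse vault, decreasing as the vault rounds. It is robust to
   slicing-plane declinations of up to ±5°.

2. **Fractional suture-fusion scoring.** Sutures are visually scored in
   fixed parts (coronal 3, lambdoid and sagittal 5, posterior frontal 2);
   group summaries report the percentage of total suture length fused and
   the signed percentage of animals affected (positive: premature closure;
   negative: widely open gap defect).

3. **Polarized Raman metrology.** Line maps across a suture are decomposed
   into eight pseudo-Voigt bands over 830–1020 cm⁻¹ (Pro ~855, Hyp ~876,
   ν₁-PO₄ ~961, Phe ~1005 among them, plus a linear baseline). The spectra
   with minimal mineral-to-matrix ratio I₉₆₁/I₁₀₀₅ localise the unossified
   suture; the package reports the mineral-to-matrix ratios (ν₁-PO₄ over
   Phe/Pro/Hyp) and crystallinity (inverse FWHM of the ν₁-PO₄ band).

A synthetic-data module generates half-ellipsoid skull phantoms (known
pose, noise and ground-truth cross-section ellipse) and synthetic bone
line maps (known band parameters and suture dip), so the entire pipeline
runs and is validated with no external data.

## Worked example

```r
library(calvaria)

# a posed, noisy 16-bit phantom with true b/a = 4500/3000 = 1.5
sp <- phantom_spec(semi_axis_dv = 3000, semi_axis_ml = 4500,
                   semi_axis_ap = 2150, shell_thickness = 150,
                   voxel_size = 25,
                   pose = list(translation = c(60, -40, 25),
                               rotation = c(horizontal = 8, sagittal = 1),
                               scale = 1.05),
                   noise_sd = 500, seed = 1)
ph <- make_skull_phantom(sp)

v8  <- convert_to_8bit(ph$volume)                       # 16-bit -> 8-bit
al  <- align_skull(v8, ph$landmarks, ph$landmarks_true) # two-stage alignment
al$transforms$horizontal
#> <similarity2d horizontal> rotation -8 deg, scale 0.952526, translation (-74.84, 817.2) um

slice_and_fit(al$volume, al$landmarks)                  # 1/4 slice + fit
#> <ellipse_fit> center (3225, 5201) um, a = 2633.2 um (dorsoventral), b = 3954.33 um (mediolateral)
#>   b/a = 1.50172, rms residual 0.00282, n = 317
```

The estimated horizontal transform undoes the phantom's pose (−8° against
the applied +8°, scale 0.9525 ≈ 1/1.05), and the fitted roundness 1.5017
recovers the ground truth 1.5 to 0.1%.

Suture scoring — four animals whose sagittal suture is fused for 1, 2, 3
and 4 fifths of its length:

```r
scores <- data.frame(skull_id = paste0("m", 1:4), suture = "sagittal",
                     parts_fused = 1:4, open_gap = FALSE)
summarize_sutures(scores, group = "erf_insufficient")
#>              group   suture n_animals pct_length_fused pct_animals_closed
#> 1 erf_insufficient sagittal         4               50                100
```

Raman line map across a synthetic suture (phosphate band halved at the
dip), fitted and localised by minimal I₉₆₁/I₁₀₀₅:

```r
tr  <- raman_truth(noise_sd = 4.4, seed = 1)
map <- make_raman_linemap(tr, n_points = 30,
                          suture_profile = suture_dip_profile(30, depth = 0.5))
summarize_linemaps(list(map))
#>          metric    mean sd n
#> 1       PO4_Phe 1.26620 NA 1   # plateau ratio 2.5, halved at the suture
#> 2       PO4_Pro 1.62294 NA 1
#> 3       PO4_Hyp 1.82991 NA 1
#> 4 crystallinity 0.08565 NA 1   # 1 / fwhm(961) = 1/11.7 cm
```

`run_demo()` chains everything: it builds a flatter "control-like" cohort
(truth b/a 1.5) and a rounder "synostotic-like" cohort (1.3), aligns, fits
and tabulates every skull, and writes per-skull JSON fits, a group table
and a declination-sweep table stamped with the config hash and seed.

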