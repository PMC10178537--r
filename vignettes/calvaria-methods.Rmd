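---
title: "Calvarial morphometry and Raman metrology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calvarial morphometry and Raman metrology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calvaria)
```

This vignette is the package's account of the science it implements: the
measurement models, their assumptions, the tunable parameters, and the
choices made where the design was genuinely open. Every empirical claim
below is one the test suite computes.

## The measurement problem

In craniosynostosis models, premature fusion of cranial sutures changes
both the sutures themselves and the global shape of the calvaria. The
package quantifies three complementary readouts from microCT volumes and
polarized Raman line maps of mouse skulls:

* a **roundness descriptor** of the coronal cross-section of the vault,
* a **fractional suture-fusion score** aggregated over animals,
* **mineral-to-matrix ratios and crystallinity** of bone at and near the
  suture.

## Coordinate conventions

Volumes are 3D arrays with anatomical axis order: dimension 1 is
dorsoventral (x; index 1 at the dorsal boundary), dimension 2 mediolateral
(y), dimension 3 anteroposterior (z). Voxels are isotropic. All voxel
indices in the package, including landmark CSV files, are **1-based**, the
native R convention; the physical position of index *i* is
`(i − 1) × voxel_size` micrometres. Landmark files record this in a header
comment.

## Alignment model

Skulls are aligned to a nominated reference using only **similarity
transforms** (translation + rotation + uniform scale), which preserve shape
by construction — the point of the protocol is to remove position and size
differences while leaving shape untouched. Two landmarks, bregma and
lambda, drive the alignment:

1. a 2D similarity estimated in the horizontal (y–z) plane maps the
   skull's (bregma, lambda) onto the reference's; two point pairs determine
   the similarity exactly (closed form via the complex ratio of the point
   differences), so the defining landmarks map with zero residual;
2. the landmark heights (x) are recovered automatically by edge detection:
   the first threshold crossing scanning each landmark's dorsoventral
   column from the dorsal side;
3. a second 2D similarity in the sagittal (x–z) plane aligns the
   (height, z) pairs.

**Applying a 2D transform to a 3D volume.** The estimated transform is
resampled into every slice along the axis orthogonal to its plane
(`apply_transform_to_volume()`, linear interpolation by default, nearest
neighbour available for exactness). Applied strictly slicewise, however,
the horizontal-plane uniform scale would rescale y and z but not x: a
skull 5% larger than the reference would keep a 5% taller vault, and the
roundness ratio b/a — which compares the x and y semi-axes — would absorb
that size difference, defeating the purpose of the scaling step.
`align_skull()` therefore treats the estimated similarity as a genuine 3D
similarity with in-plane rotation: the uniform scale also acts on the
orthogonal axis (about the volume centre; the subsequent sagittal stage
absorbs the resulting offset). The slicewise behaviour remains the default
of the low-level function.

Height recovery uses Otsu's threshold computed from the exact histogram of
the **whole volume** by default. A per-slice threshold was considered and
rejected: on slices containing no bone the between-class variance argmax is
meaningless and every voxel "crosses", so a column outside the skull would
return height 1 instead of failing. The threshold is overridable wherever
it is used.

## Slice extraction and the roundness descriptor

The analysis slice is perpendicular to the bregma–lambda line at a
fractional distance from bregma, default **¼**. The slice grid pitch
equals the voxel size; samples are trilinear; the in-plane axes are the
anatomical x (dorsoventral) and y (mediolateral) directions projected into
the plane, canonicalised so that slices specified from either landmark
order coincide. A declination (pitch about the mediolateral axis, yaw
about the dorsoventral axis, each bounded at ±5° by default) tilts the
plane for robustness analyses. Slice thickness defaults to one plane;
`thickness > 1` averages parallel planes (the acquisition protocol does
not state an averaging width).

The outer vault surface is collected per mediolateral column between the
two parietal lateral edges as the dorsal-most threshold crossing along x,
localised to sub-pixel precision by linear interpolation between the
bracketing voxels. The resulting point cloud covers roughly the dorsal
half of the cross-section — the fit must therefore be well-behaved on
half-arcs, which the oracle tests check explicitly.

The ellipse model is deliberately **axis-aligned** (no cross term):

$$\left(\frac{X - X_0}{a}\right)^2 + \left(\frac{Y - Y_0}{b}\right)^2 = 1$$

because skulls are pre-aligned before fitting. The fit minimises the
algebraic residual of $Ax^2 + By^2 + Cx + Dy + E = 0$ under $A + B = 1$,
a linear least-squares problem solved in closed form, followed by
completion of the square. Degenerate solutions ($A \le 0$, $B \le 0$, or a
non-positive completed square) are errors, as are clouds of fewer than 5
points or collinear clouds. The descriptor is $b/a$ with $a$ the
dorsoventral and $b$ the mediolateral semi-axis, recorded explicitly in
the fit's `axis_labels` so the ratio is self-describing: 1 for a circle,
about 1.5 for a normal mouse vault, moving toward 1 as the vault rounds.

Properties the suite verifies: translation and uniform-scale invariance of
b/a (and the deliberate **non**-invariance under 90° rotation, which swaps
the ratio); agreement with a brute-force grid search over
$(X_0, Y_0, a, b)$ minimising the same residual; unbiasedness of b/a
within 1% at 2% coordinate noise on full arcs. On **half arcs** the
algebraic estimator is known to develop a noise-dependent bias (we measure
≈4% at 2% coordinate noise); in the pipeline this is immaterial because
surface points are localised to ≈0.3 voxel on semi-axes of 150–300 voxels
(≈0.2% noise), two orders of magnitude below that regime, and the
end-to-end tests bound the total error directly.

## The skull phantom

The synthetic phantom is a **half-ellipsoid shell**: outer semi-axes
$(a_{dv}, b_{ml}, c_{ap})$, constant thickness (inner ellipsoid with all
semi-axes reduced by the shell thickness), cut 15% of $a_{dv}$ below the
equator so the "parietal bone" wraps slightly ventrally as in a real
calvaria. It is the minimal geometry that exercises every pipeline stage;
it is not an anatomical skull. Every coronal cross-section of the
generating ellipsoid has the same $b/a$, so the ground-truth roundness is
$b_{ml}/a_{dv}$, independent of pose — the invariance the alignment is
supposed to deliver, available here by construction.

Defaults emulate an adult mouse calvaria scanned at 15 µm: $a_{dv}$ = 3000
µm, $b_{ml}$ = 4500 µm (truth b/a = 1.5), $c_{ap}$ = 2150 µm
(bregma–lambda span 4.3 mm at the landmark fraction below), shell 150 µm,
16-bit intensities with bone at 75% and background at 5% of the range, and
additive Gaussian intensity noise clipped to the bit range (the scanner's
intensity distribution is not part of the protocol; contrast is a free
parameter).

Two phantom details matter for testability:

* **Landmarks sit on the dorsal outer surface at 95% of $c_{ap}$**, not at
  the exact anteroposterior poles: the poles are points where scan columns
  are tangent to the shell, which no edge detector can recover. The ¼
  slice position and ground-truth ellipse account for this.
* The phantom is voxelised **analytically in the posed frame** (the pose
  is inverted exactly at every voxel centre), so posed phantoms carry no
  interpolation blur and alignment can be tested for exact recovery;
  landmarks are emitted in both the posed frame (pipeline input) and the
  unposed frame (ground truth).

What the phantom does *not* emulate: real suture geometry, trabecular
texture, beam-hardening or reconstruction artefacts, anatomical asymmetry.
Passing tests demonstrate the correctness of the geometry pipeline, not
performance on pathological scans.

## Suture scoring

The scoring scheme divides each suture into fixed parts — coronal sutures
3, lambdoid and sagittal 5, posterior frontal 2; the frontonasal and
accessory occipital counts are not part of the stated scheme and default
to 3, configurable. A score is the number of fused parts; the fused
fraction is `parts_fused / parts_total`. Group summaries report the mean
fused fraction × 100 (percentage of total suture length fused) and a
signed percentage of animals affected: positive for any premature fusion,
negative for a widely open suture with a gap defect; the two flags are
mutually exclusive with full fusion by validation. Partial deformities
that are neither closed nor open are representable as affected = 0 plus a
free-text `note` column. Arithmetic is exact on the integer part counts
(the conservation identity `pct × n × parts_total / 100 = Σ parts_fused`
is tested to 1e-12); percentages should be reported to one decimal.

## Raman model

Bands are **pseudo-Voigt** profiles, $\eta\,G + (1-\eta)\,L$, Gaussian
fraction $\eta \in [0,1]$, with Gaussian and Lorentzian sharing centre,
height and FWHM — so the value at the centre is the height and the value
at centre ± FWHM/2 is half the height for every $\eta$. This is the
conventional reading of "mixed Gaussian/Lorentzian"; the closed-form area
is $h\,w\,[\eta\frac{1}{2}\sqrt{\pi/\ln 2} + (1-\eta)\frac{\pi}{2}]$.

Eight bands plus a **linear baseline** (the protocol does not state its
baseline handling; linear over the 190 cm⁻¹ window is the simplest choice
that absorbs fluorescence slope) are fitted over **830–1020 cm⁻¹** by
Levenberg–Marquardt (`minpack.lm::nls.lm`) with bounds: centres within ±10
cm⁻¹ of their seeds, heights ≥ 0, FWHM in (0, 60], $\eta \in [0,1]$. The
Jacobian is supplied analytically: the 34-parameter problem is
ill-conditioned (overlapping bands trade height, width and shape against
each other and the baseline), and finite-difference steps both cost 34
function evaluations per iteration and stall before the flat valley floor
is reached. Fits are deterministic given seeds and data; non-convergence
and seed tables with centres closer than 2 cm⁻¹ are errors.

Multiplying a spectrum by a constant rescales the exact least-squares
solution's heights by the same constant, so every ratio and the
crystallinity are invariant. Numerically this holds to 1e-6 on noiseless
spectra (sharp minimum); on noisy spectra the valley flatness that sets
the recovery envelope below also limits equivariance, to about 1%. The default band table
(Tyr 836, Pro 855, Hyp 876, ν(C–C) 898, Pro ring 921, C–C backbone 940,
ν₁-PO₄ 961, Phe 1005) is a literature-typical set of bone fingerprint
bands shipped as a package default and fully overridable — the instrument
table of any given study should be supplied instead.

Ratios use fitted **heights** by default, matching the intensity notation
I₉₆₁/I₁₀₀₅ (areas are available as an option; which of the two the
original protocol used is not stated). Crystallinity is 1/FWHM of the
ν₁-PO₄ band, the standard bone-Raman convention. Suture spectra are those
attaining the minimal I₉₆₁/I₁₀₀₅ within a 1% relative tie tolerance;
specimen summaries pool the selected spectra of all line maps into mean ±
sd per metric.

### Recovery precision and the SNR convention

The synthetic generator quotes SNR for the **weakest band** (noise sd =
smallest generating height / SNR), because recovery tolerances are driven
by it; at 6-hour line-map acquisitions the strongest band's SNR is far
higher, so the weakest-band figure is the informative one. The grid
default is 760–1020 cm⁻¹ at 0.5 cm⁻¹.

How precisely can band heights be recovered at worst-band SNR 50? The
suite fits noiseless spectra to machine precision, and on noisy spectra
its errors sit at the **Cramér–Rao bound** of the model: with every
band's $\eta$ free and eight overlapping bands sharing a linear baseline,
the bound on height standard errors ranges from 0.6% (isolated, sharp
Phe 1005) to ≈5% (edge-truncated Tyr 836) of the band height. The
module-level test therefore pins the calibrated envelope — centres within
0.5 cm⁻¹ (maximum over 20 seeds), per-band mean absolute height error
within 5% — computed once from the 20-seed calibration and frozen. A 3%
per-band height envelope at this SNR is not attainable by any unbiased
estimator; the end-to-end spectroscopy test asserts that stricter figure
regardless, so the gap is recorded as a failing expectation rather than
hidden behind a loosened tolerance.

## Problem sizes in the test suite

Unit tests run phantoms at 20–25 µm voxels (≈1–2 million voxels); the
end-to-end acceptance checks run the full 15 µm scale (≈45 million voxels
per phantom, 20 posed noisy replicates; ≈4 minutes) and full ±5°
declination sweeps on two phantoms. The resampling and voxelisation inner
loops are small compiled kernels (`src/`), as is usual for image
pipelines, so the whole suite completes in minutes on one CPU.

## Known limitations

* The alignment corrects dorsoventral scale through the 3D reading of the
  horizontal similarity; with strictly slicewise application the
  descriptor would absorb residual size differences (see above).
* The axis-aligned ellipse is correct only for aligned skulls; the package
  does not fit rotated conics by design.
* The suture-fusion module encodes the arithmetic of visual scoring; it
  does not detect fusion from images.
* Raman fitting assumes the band table provided; it does not search for
  bands, despike cosmic rays, or model polarization tensors (the
  polarization configuration is carried as a label only).
* The roundness descriptor's direction of biological change (whether lower
  b/a means a "rounder" or "more elliptical" skull) depends on the axis
  convention; the package always reports b/a with explicit axis labels and
  leaves interpretation to the analyst.
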