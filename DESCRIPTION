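Package: calvaria
Title: Morphometry and Raman Metrology of the Murine Calvaria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of skull-vault morphology and bone
    composition for mouse models of craniosynostosis. Provides
    landmark-constrained similarity alignment of microCT volumes, extraction
    of a coronal slice at a fractional position along the bregma-lambda
    axis, least-squares fitting of an axis-aligned ellipse to the outer
    calvarial surface yielding the b/a roundness descriptor, a fractional
    suture-fusion scoring scheme with group aggregation, and pseudo-Voigt
    decomposition of polarized Raman line maps into bone mineral and matrix
    bands with mineral-to-matrix ratio and crystallinity metrology. A
    synthetic-data module generates half-ellipsoid skull phantoms and bone
    Raman line maps with known ground truth so the full pipeline is testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    RNifti,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
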