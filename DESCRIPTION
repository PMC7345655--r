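Package: dvc3d
Title: Digital Volume Correlation for 3-D Deformation and Strain Mapping of
    Fibrous Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Subset-based three-dimensional digital volume correlation (DVC)
    for quantifying full-field deformation and strain of fibrous,
    extracellular-matrix-like media imaged by volumetric coherent microscopy
    (e.g. optical coherence microscopy of collagen gels). Provides a
    synthetic speckle-phantom generator with exactly known deformations
    (integer-voxel rolls, Fourier-shift-theorem subvoxel translations,
    affine and localized traction-like fields), normalized cross-correlation
    displacement estimation with subpixel peak localization and iterative
    multi-pass refinement, per-depth-stack drift correction, incremental to
    cumulative displacement accumulation for time-lapse series,
    infinitesimal strain tensor mapping by plane-averaged central
    differences, and validation protocols that measure the error floor and
    virtual-translation accuracy across transverse sampling rates. Volumes
    are read and written as multi-page TIFF stacks with voxel-spacing
    metadata; fields export to legacy VTK for 3-D rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
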