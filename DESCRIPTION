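Package: sisfdi
Title: Speckle-Illumination Spatial Frequency Domain Imaging with Profile
    Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates per-pixel absorption and reduced scattering
    coefficient maps of turbid media from a single laser-speckle (AC) image
    and a single speckle-reduced (DC) image, the speckle-illumination
    variant of spatial frequency domain imaging. Modulation is measured by
    sliding-window autocorrelation and radial power spectral density,
    calibrated against a reference phantom, and inverted through a
    diffusion-approximation diffuse-reflectance lookup table. Active-stereo
    profilometry (normalized cross-correlation pyramid matching, point
    cloud smoothing, local plane-fit normals) supplies per-pixel height and
    surface angle, which drive a virtual-reference height correction and a
    Lambertian 1/cos(theta) angle correction of the calibrated reflectance.
    A synthetic-scene simulator (fully developed speckle, tissue MTF
    filtering, laser-speckle-reducer averaging, Lambertian shading, pinhole
    stereo rendering) makes the whole pipeline testable without
    instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    signal,
    stats,
    tiff,
    png,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
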