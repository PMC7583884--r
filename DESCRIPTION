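Package: ovospec
Title: Egg Freshness Grading from Scattering Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for grading egg freshness from hyperspectral
    images acquired under different illumination geometries (dome reflection,
    transmission, and fiber-optic scattering at incident angles 0-60 degrees).
    Includes a synthetic-scene generator with Haugh-unit-driven spectra,
    black/white reflectance correction and an ENVI-dialect reader/writer,
    automatic elliptical region-of-interest extraction, ten chemometric
    preprocessing methods (MSC, SNV, normalization, autoscaling, mean
    centering, moving average, detrending, and the Savitzky-Golay family),
    wavelength selection by PCA, the successive projections algorithm (SPA)
    and competitive adaptive reweighted sampling (CARS) over a PLS1 core, six
    weak classifiers behind one contract, a two-layer stacking ensemble with
    out-of-fold meta-features, and an incident-angle accuracy report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
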