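Package: honeyspec
Title: Hyperspectral Transmittance Simulation and Sum-of-Sines
    Classification of Honey Adulteration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates transmission hyperspectral microscopy cubes of
    honey/syrup mixtures, reduces them to per-neighborhood transmittance
    spectral curves, compresses each curve to a 24-coefficient sum-of-sines
    fingerprint by nonlinear least squares, and classifies adulteration
    level with cross-validated linear discriminant analysis, quadratic-kernel
    support vector machines, and a ReLU feed-forward network, reporting
    per-class precision, recall, specificity, F1 and overall accuracy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    e1071,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
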