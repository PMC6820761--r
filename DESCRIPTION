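Package: ftirsim
Title: Simulation of FT-IR Imaging Hyperspectral Datasets with Experimentally Matched Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generates noise-free and noise-corrupted hyperspectral FT-IR
    imaging datasets of a simulated tissue core. Spectra are sums of
    randomized Voigt bands built from a packaged band table, arranged
    spatially by synthetic class-concentration maps, corrupted by a
    randomized linear scattering baseline, blurred with a
    wavelength-dependent Gaussian point-spread function, and finally
    degraded with absorbance-dependent Gaussian noise calibrated
    iteratively against a band-free-region signal-to-noise metric.
    Includes a Signal Distortion metric for benchmarking denoising
    algorithms against the known clean reference, and ENVI cube I/O.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
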