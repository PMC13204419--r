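Package: photodose
Title: Diffusion-Model Light Dosimetry for Wearable Tissue Optics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward and inverse modeling for two-distance diffuse-reflectance
    probes on homogeneous semi-infinite tissue: effective attenuation
    coefficient inversion, relative internal photon-fluence reconstruction,
    two-wavelength regional oxygen saturation estimation, and steady-state
    Pennes bioheat depth-temperature prediction. Includes a tissue-phantom
    telemetry simulator and a photon-packet Monte Carlo oracle for validating
    the diffusion approximation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
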