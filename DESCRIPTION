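Package: cortexlight
Title: Monte Carlo Simulation of Widefield Fluorescence Sources in Cortex
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Monte Carlo photon-transport simulator and analysis toolkit for
    widefield fluorescence imaging of mouse cortex. Simulates illumination
    through a cranial window or skull into layered scattering tissue,
    isotropic fluorescence emission and its collection by a low numerical
    aperture objective, and shadowing by surface blood vessels, using
    MCML-style weighted photon packets with Henyey-Greenstein scattering.
    Combines the resulting depth profiles with laminar indicator-expression
    profiles to attribute widefield fluorescence to cortical layers and to
    the tissue volume contributing to a single surface pixel.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
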