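Package: inkoptics
Title: Optical Modeling of Cell-Laden Bioinks for DLP Bioprinting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Forward Monte Carlo simulation of light transport in turbid,
    cell-laden bioink slabs, inverse estimation of scattering coefficient and
    anisotropy from integrating-sphere and goniometer observables via particle
    swarm optimization, point-spread-function convolution to predict projected
    pattern blurring in digital light processing (DLP) bioprinting, critical
    angle prism refractometry, and a refractive-index mixing model for
    iodixanol-supplemented hydrogel bioinks. Includes a synthetic measurement
    generator for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
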