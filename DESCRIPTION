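Package: imcspect
Title: Inverse Monte Carlo Spectrophotometry of Nanoparticle Suspensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modelling of spectrophotometric measurements of
    turbid nanoparticle suspensions held in a cuvette. Provides a Mie forward
    model for polydisperse silicon nanoparticle suspensions (absorption and
    scattering coefficients and the scattering anisotropy factor versus
    wavelength), a Monte Carlo photon-transport simulator of the collimated
    transmittance, diffuse transmittance and diffuse reflectance measured with
    an integrating-sphere spectrophotometer, and a lookup-table inversion that
    reconstructs the optical properties by minimising a relative least-squares
    functional. Includes spectral analysis tools (power-law exponent fits of
    the scattering coefficient, Rayleigh/Mie transition diameter, host-liquid
    absorption-peak detection) and a synthetic-data generator emulating
    laser-ablated silicon nanoparticle suspensions in water and ethanol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
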