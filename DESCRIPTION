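Package: phototherm
Title: Multiscale Temperature Fields for Nanoparticle Photothermal Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planning calculations for plasmonic-nanoparticle photothermal
    therapy across three spatial scales. Computes single-sphere Mie
    efficiencies and absorption cross-sections of gold nanospheres from
    tabulated optical constants, composite tumor attenuation coefficients
    from nanoparticle loading with Beer-Lambert depth attenuation,
    steady-state temperature-rise fields by superposition of clamped
    point-source kernels at the nanoparticle, cell, and tissue scales
    (direct compiled summation and an FFT particle-mesh fast path),
    parameterized irradiation footprints (full-coverage, spot, ring, and
    spot-array beams), and Arrhenius thermal-damage and overheating
    summaries for therapy quality assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
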