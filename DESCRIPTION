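Package: colloidcrowd
Title: Colloidal Multiscale Analysis of Crowded Protein Solutions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models crowded globular-protein solutions as polydisperse hard
    spheres with weak short-ranged attraction. Provides Schulz-polydispersity
    scattering theory (form factors, intensity-averaged radii, ellipsoid
    Rh/Rg maps), sticky-hard-sphere and square-well interaction relations
    (Kd, stickiness, second virial coefficients, Carnahan-Starling and
    polydisperse Percus-Yevick compressibility), an event-driven molecular
    dynamics engine for polydisperse square-well spheres with effective
    structure factors, the dynamic-light-scattering / small-angle-scattering /
    neutron-spin-echo / tracer-microrheology fitting chain (cumulant,
    stretched-exponential, Guinier, arrest power-law fits), and synthetic-data
    generators with known ground truth for every input the analysis consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
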