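Package: coswater
Title: Polarizable Charge-on-Spring Water Model Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating a rigid four-site polarizable
    water model with charge-on-spring (Drude-like) induced dipoles and
    higher-order C6-C8-C11 dispersion. Provides a consensus (multi-frame
    constrained) least-squares method to extract condensed-phase
    polarizabilities from induced electrostatic potentials, a synthetic
    generator for solvent point-charge shells and Connolly-grid potentials,
    electrostatic-potential charge fitting with an off-site position scan,
    a compact polarizable molecular dynamics engine (leap-frog, SHAKE,
    self-consistent charge-on-spring displacements, reaction-field
    electrostatics, Berendsen thermostat and barostat), and estimators for
    pure-liquid properties such as density, heat of vaporization, static
    dielectric permittivity, self-diffusion with finite-size correction, and
    fluctuation-based response properties.
License: MIT
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
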