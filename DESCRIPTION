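Package: cdicolony
Title: Individual-Based Simulation of Contact-Dependent Growth Inhibition in
    Expanding Bacterial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An individual-based model of contact-dependent growth inhibition
    (CDI) in two-dimensional expanding bacterial colonies. Cells are rigid
    capsules that elongate exponentially, divide at a stochastic target
    length, and resolve overlaps through iterated pairwise relaxation, so
    that growth is mechanically suppressed in the jammed colony interior and
    concentrated at the expanding edge. Inhibitor cells intoxicate touching
    target cells after a stochastic contact time governed by an exact
    Gibson-Bruck next-reaction scheduler over the dynamic contact graph;
    intoxicated targets grow at a reduced rate and may recover after losing
    inhibitor contact. The package includes the quantification suite used to
    characterise competition outcomes in such colonies (neighbor index,
    radial annulus composition, sector frequency and sector size via
    iterated circular Gaussian smoothing, relative fitness) and a
    command-line interface for reproducible runs, parameter sweeps and
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
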