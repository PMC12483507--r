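Package: hoverwing
Title: Allometric Scaling of Wing Morphology and Wingbeat Kinematics in
    Hovering Flight
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how flying insects maintain weight
    support across body sizes. Computes wing-outline morphometrics
    (area, span, chord, second-moment-of-area, semi-landmark Procrustes
    shape analysis and phylogenetic PCA), wingbeat-kinematics summaries
    from stroke/deviation/rotation angle time series (Fourier fits,
    angular speed, angle-of-attack, advance ratio), a quasi-steady
    aerodynamic force model for hovering, and a scaling framework that
    compares fitted log-log allometric exponents (OLS and phylogenetic
    GLS under Brownian motion, Blomberg's K) against geometric- and
    kinematic-similarity baselines and single-metric weight-support
    baselines to decompose the relative contribution of wing size,
    shape, and wingbeat kinematics to weight support. Includes a
    synthetic-data generator (pure-birth phylogenies, Brownian-motion
    body masses, parametric wing outlines, periodic wingbeat traces)
    so the full pipeline is testable without flight recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    nlme,
    phytools,
    vegan,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
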