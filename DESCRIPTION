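Package: wkloop
Title: Windkessel-Laplace Afterload Simulation for Cardiac Muscle Work-Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Deterministic virtual-experiment simulator for isolated cardiac
    trabeculae contracting against a three-element Windkessel model of arterial
    impedance. Muscle force and length are mapped to ventricular pressure and
    volume through a thin-walled spherical (Laplace) ventricle, the aortic
    valve is an ideal diode, and the coupled hybrid system is advanced on a
    fixed 50 microsecond grid, mirroring real-time work-loop control hardware.
    Provides replay of recorded twitch-force traces, a Hill-type muscle
    fixture for closed-loop adaptation studies, an isotonic (flat-topped
    work-loop) afterload controller, parameter sweeps and abrupt parameter
    steps, disease-condition presets, and pressure-volume and work-loop
    analysis (loop areas, stroke volume, diastolic decay fits,
    work-afterload relations).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
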