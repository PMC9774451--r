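Package: ocufield
Title: Electric Field Simulation and Stimulation-Locality Evaluation for
    Periocular Electrode Montages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based design of transcranial alternating current
    stimulation (tACS) electrode montages that locally stimulate sub-regions
    of the lower ocular surface. Provides a synthetic head/orbit tissue
    phantom with embedded eyeballs, a piecewise-linear finite-element solver
    for the quasi-static volume-conduction equation with electrode boundary
    conditions, signed (phase) superposition of multi-pair drives, an
    analytic conducting-sphere oracle for solver validation, and the
    ocular-surface evaluation layer: spherical unwrapping of the eyeball
    surface field, longitude/latitude grid interpolation, region
    partitioning, and locality metrics based on in-region versus
    out-of-region field maxima.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    interp,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
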