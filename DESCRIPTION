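Package: hyaloSF
Title: Biophysical Analysis of Hyaluronan in Synovial Fluid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing hyaluronan (HA) and its heavy-chain
    complexes in synovial fluid. Computes molecular-weight distributions and
    their summaries (Mw, Mn, polydispersity) from agarose-gel densitometry
    with ladder calibration and rolling-ball background subtraction, and from
    solid-state nanopore current traces via robust baseline estimation,
    threshold event detection, event-charge-deficit (ECD) integration and
    calibration against quasi-monodisperse standards. Estimates fluid
    viscosity from multiple particle-tracking microrheology trajectories
    through mean-squared displacement and the Stokes-Einstein relation.
    Quantifies heavy chain-HA (HC-HA) complex from paired immunoblot band
    densities, and provides the cohort statistical layer: normality-gated
    two-group tests with skew-directed transforms, 2^-ddCt fold changes,
    five-parameter logistic immunoassay calibration, Spearman correlation,
    constrained quadratic viscosity-concentration fits, intra-assay CV and
    replicate filtering. Seeded synthetic-data generators for every input
    modality make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm,
    e1071,
    jsonlite,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
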