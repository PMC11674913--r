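Package: depcyto
Title: Dielectrophoresis-Imaging Flow Cytometry Modelling and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis stack for a dielectrophoresis (DEP)
    imaging flow cytometer. Provides double-shell dielectric models of
    single cells and the Clausius-Mossotti spectrum, a finite-difference
    electrostatic solver for the field above a coplanar electrode pair,
    overdamped particle-transport simulation in a parallel-plate channel
    (drag, lift, gravity/buoyancy, DEP), forward mapping and inversion
    from tracked velocities to the real part of the Clausius-Mossotti
    factor, a synthetic quasi-darkfield video generator with ground
    truth, a cell detection/linking/velocimetry pipeline, and
    Gaussian-mixture discrimination of viable and non-viable
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
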