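Package: polforce
Title: Molecular Force Orientation Mapping from Polarization-Modulated
    Structured-Illumination Microscopy
Version: 0.1.0
Authors@R:
    person("polforce", "maintainers", email = "polforce@example.org",
           role = c("aut", "cre"))
Description: Recovers per-pixel molecular force orientation (in-plane angle
    phi, tilt angle theta) and a magnitude proxy (Imax) from
    polarization-modulated structured-illumination (SIM) image montages of
    molecular tension probes. Implements the closed-form three-angle
    sinusoid fit, the montage preprocessing recipe (baseline subtraction,
    flat-field correction, phase averaging), Monte Carlo characterization
    of orientation measurement error, timelapse analysis of cell traction
    dynamics (tension area and force-alignment kinetics fit by simulated
    annealing), orientation-map rendering, and a synthetic-data generator
    emulating platelet tension scenes so that the whole pipeline is
    testable without microscope data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
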