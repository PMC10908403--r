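Package: pwva
Title: Noninvasive Pulse-Wave Indices of Vascular Aging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes nineteen noninvasive pulse-wave indices of vascular
    aging (pulse wave velocities, pressure-derived indices, wave-separation
    quantities, the cardio-ankle vascular index, carotid distensibility and
    photoplethysmogram-derived indices) from multi-site single-beat pressure,
    flow-velocity, luminal-area and photoplethysmogram waveforms, and assesses
    them against an exact reference aortic stiffness (the length-weighted
    aortic Young's modulus from the Olufsen wall law).  Includes a synthetic
    virtual-subject generator with known ground truth, signal-to-noise
    controlled Gaussian noise injection with zero-phase band-pass filtering,
    fiducial-point detection for pressure and photoplethysmogram beats, and a
    statistical harness (correlations with age subgroups, Bland-Altman
    agreement, relative sensitivity indices, noise-robustness tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
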