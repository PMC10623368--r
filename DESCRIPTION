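Package: lithocav
Title: Cavitation Physics of Kidney-Stone Dusting in Ho:YAG Laser Lithotripsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the physics of stone dusting
    in Holmium:YAG laser lithotripsy. Covers the full computational chain from
    laser energy partition to shock-solid damage: voxelized Monte Carlo photon
    transport through water, vapor bubble and stone; axisymmetric transient
    heat-conduction ablation with multi-pulse crater evolution; superheating
    bubble-inception energetics and Rayleigh bubble dynamics; hydrophone
    waveform analysis (significant-peak selection, 1/r scaling, pressure
    impulse, acoustic emission energy, toroidal-bubble geometry); an
    axisymmetric fluid-solid elastodynamic wave solver resolving leaky
    Rayleigh and Schmidt head waves; and Tuler-Butcher cumulative damage
    assessment. Includes seeded synthetic-data generators emulating the
    experimental inputs (power profiles, bubble geometry sequences,
    radius-time curves, hydrophone traces, silhouette images).
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
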