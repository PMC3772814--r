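Package: elastofilt
Title: Biomechanical-Model-Constrained H-Infinity Filtering for
    Quasi-Static Ultrasound Elastography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering full two-dimensional displacement and
    strain fields in quasi-static ultrasound elastography.  Axial
    displacement is estimated from pre/post-compression radio-frequency
    frame pairs by phase-shift estimation with prior-lag phase
    unwrapping.  Sparse, noisy displacement measurements are then fused
    with a plane-strain linear-elastic finite-element model through a
    game-theoretic H-infinity filter, which bounds the worst-case energy
    gain from disturbances to estimation error without requiring noise
    statistics.  All five plane-strain strain images (axial, lateral,
    axial-shear, lateral-shear and shear) are derived from the recovered
    displacement field.  A synthetic phantom generator (stiff circular
    inclusion in a soft background under uniaxial compression, with
    typed noise at controlled signal-to-noise ratios) supports
    simulation studies, and a tissue-incompressibility baseline and
    evaluation metrics (error-to-displacement ratio, contrast-to-noise
    ratio, nodal positional error) support method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
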