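Package: csfpulse
Title: Cardiac-Gated Phase-Contrast MRI Simulation and CSF Flow Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pulsatile cerebrospinal fluid (CSF) flow in
    the spinal canal from cardiac-gated phase-contrast MRI. Includes a digital
    phantom generator with known ground truth (velocity-encoded phase images
    with aliasing, background phase offsets and Rician magnitude noise), a
    reconstruction stage (temporal phase unwrapping, polynomial background
    correction, velocity scaling by the velocity-encoding limit), computation
    of six cardiac-cycle flow metrics (cranial and caudal flow volume, net and
    absolute stroke volume, flow-rate amplitude and peak flow rate), a
    synthetic cohort generator with configurable age and biomarker correlation
    structure, and an age-adjusted association stage (Spearman/Pearson
    correlation matrices, partial correlation computed by two cross-checked
    routes, and residualization regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
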