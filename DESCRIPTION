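Package: rangewepl
Title: Inter-Fraction Proton Range Uncertainty from Serial Volumetric CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies random (inter-fraction) proton range uncertainty from
    serial volumetric CT imaging. Provides Bethe-Bloch based conversion of CT
    numbers to relative proton stopping power, per-pixel water-equivalent
    path length (WEPL) ray tracing toward a coplanar beam focus, rigid-shift
    registration and field-of-view truncation correction of daily images,
    per-fraction WEPL-difference distributions within the clinical target
    volume, and population-level systematic (Sigma) and random (sigma) range
    error statistics suitable as priors for robust treatment-plan
    optimisation. Includes a ground-truthed synthetic phantom course
    generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
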