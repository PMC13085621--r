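Package: dvos
Title: Dynamic Vascular Optical Spectroscopy Analysis for Peripheral Arterial Disease
Version: 0.1.0
Authors@R:
    person("DVOS", "Maintainers", email = "maintainers@dvos.invalid", role = c("aut", "cre"))
Description: Simulation and analysis of dynamic vascular optical spectroscopy
    (DVOS) recordings acquired under a five-phase thigh cuff-occlusion protocol.
    Provides a calibrated synthetic cohort generator (covariates and hemodynamic
    ground truth for diabetic subjects with and without peripheral arterial
    disease), a modified Beer-Lambert forward and inverse optical model, channel
    quality control and zero-phase Butterworth filtering, extraction of the four
    occlusion hemodynamic parameters (change in oxyhemoglobin, hemoglobin flow,
    tissue oxygen consumption, and HbT plateau time), and the group-comparison
    and covariate-adjusted cross-validated classification statistics used to
    assess their diagnostic value.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
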