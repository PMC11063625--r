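Package: emospike
Title: Single-Unit and Population Analysis of Human MTL Spiking During
    Emotional Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microwire single-unit recordings from the
    human medial temporal lobe (hippocampus, amygdala, entorhinal cortex)
    during an emotional memory task. Provides unit quality control and
    artifact-spike removal, baseline-versus-stimulus permutation tests of
    event responsiveness, a factorial-ANOVA census of emotion-, memory- and
    interaction-selective neurons with shuffled-label bootstrap null
    distributions, an abs(z) linear mixed-effects population summary with
    nested patient/neuron random intercepts, and a from-scratch demixed
    principal component analysis (dPCA) with cross-validated decoding
    significance, PCA baseline and leave-one-region-out reruns. Includes an
    inhomogeneous-Poisson spike-train simulator with planted emotion and
    subsequent-memory effects for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    car,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
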