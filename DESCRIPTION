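Package: neurofuzz
Title: PSO-Initialised Fuzzy C-Means Segmentation and ALFF Analysis of Brain MR Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fuzzy C-means (FCM) tissue segmentation of noisy brain
    magnetic-resonance images with particle-swarm-optimised (PSO) cluster
    initialisation, adaptive median denoising and Jaccard evaluation, together
    with a resting-state amplitude-of-low-frequency-fluctuation (ALFF/zALFF)
    analysis stage with motion quality control, ROI group statistics and ROC
    discrimination. A seeded phantom generator produces ground-truthed
    multi-tissue images and 4D BOLD series so the whole pipeline runs and is
    testable without any acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, RNifti, jsonlite
Suggests: testthat (>= 3.0.0), e1071, pROC, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
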