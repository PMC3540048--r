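Package: phmri
Title: Pharmacological fMRI Infusion-Response Analysis with Spatially Regularized Mixture Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacological fMRI (phMRI) drug-infusion
    studies with a paired crossover design. Implements single-subject
    voxelwise GLM analysis of a ramped infusion response (with singular value
    decomposition onset-nuisance regressors, linear drift and white-matter /
    cerebrospinal-fluid covariates), paired group-level contrasts between two
    drug conditions, spatially regularized Gaussian-mixture inference with a
    Markov random field soft-max label prior estimated by iterated conditional
    modes, posterior probability maps thresholded at 0.5, and seed-based
    partial-correlation functional connectivity on the steady-state window.
    Ships a synthetic crossover phantom with known ground truth so every stage
    is testable end to end, plus cluster-table reporting with laterality, peak
    statistic, peak world coordinates and cluster volume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
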