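Package: qmriMorph
Title: Quantitative MRI Brainstem Morphometry with Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative MRI (qMRI)
    morphometry of the brainstem in spinal cord injury. Provides a multi-echo
    FLASH phantom simulator with ground-truth tissue geometry and
    diffeomorphic deformations; estimation of magnetisation-transfer
    saturation (MTsat), longitudinal relaxation rate (R1) and effective
    transverse relaxation rate (R2*) maps from dual-flip-angle multi-echo
    acquisitions; population tissue-probability-map learning with a
    multivariate Gaussian mixture fit by Expectation-Maximization under
    spatially varying priors; stationary-velocity diffeomorphic registration
    with Jacobian-determinant maps for tensor-based morphometry;
    voxel-based quantification with general-linear-model contrasts and
    Gaussian-random-field cluster-level family-wise-error inference; and an
    ISNCSCI/SCIM clinical scoring layer with cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
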