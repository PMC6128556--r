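Package: petgpr
Title: Predicting Cognitive Performance from Brain Metabolism with
    Linear-Kernel Gaussian Process Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based prediction of neuropsychological principal
    components from resting-state FDG-PET brain metabolism volumes.
    Implements the full analysis pipeline: volume preprocessing (Gaussian
    smoothing, factor-2 downsampling, brain masking, global-mean scaling,
    voxelwise age residualization), PCA of a neuropsychological battery
    with per-measure contributions, linear-kernel Gaussian-process
    regression fitted in the dual (Gram) form with primal weight-map
    extraction, leave-one-out cross-validation with permutation
    significance testing, and group-comparison statistics (pooled t,
    Cohen's d, chi-square) from raw data or printed summary statistics.
    A synthetic-cohort generator with a planted spatial signal makes every
    stage testable without patient scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
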