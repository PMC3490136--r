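Package: fenica
Title: Fully Exploratory Network ICA for Multi-Study Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Template-free group analysis of resting-state fMRI by fully
    exploratory network independent component analysis (FENICA): per-subject
    spatial ICA with automated model-order estimation via the Laplace
    approximation to the probabilistic-PCA evidence, group components built by
    cross-subject matching and averaging of single-subject component maps,
    ranked by voxelwise t-sums and deduplicated by a data-driven similarity
    threshold. Includes subject- and study-level consistency assessment
    (Kolmogorov-Smirnov distance clustering, bidirectional partner matching),
    spectral characterization of network timecourses (dynamic range, power
    ratio), robust meta-regression of model order on scan duration, and a
    multi-study synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    RNifti,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
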