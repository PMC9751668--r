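Package: perfpaint
Title: Perfusion-Guided Dose Painting for Brain Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A simulation and evaluation pipeline for dose-painting
    radiotherapy of single brain metastases guided by cerebral blood flow
    (CBF) maps from arterial spin labeling MR perfusion. Provides seeded
    synthetic head phantoms with heterogeneous tumor perfusion, threshold
    segmentation of hypoperfused boost subvolumes (below 25 percent of the
    within-tumor maximum CBF), physical-distance margin expansion on
    anisotropic voxel grids, a synthetic dose model emulating conventional
    and simultaneous-integrated-boost prescriptions with maximum-dose caps
    and coverage normalization, dose-volume histogram metrics (D2%, D98%,
    Dmean, coverage, Paddick conformity index, index of achievement), and
    cohort-level comparison statistics (one-way ANOVA with LSD pairwise
    tests and between-plan increment percentages).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'grid.R'
    'blur.R'
    'mask.R'
    'geometry.R'
    'dosemodel.R'
    'dvh.R'
    'cohort.R'
    'io.R'
    'phantom.R'
    'segmentation.R'
    'reference.R'
    'pipeline.R'
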