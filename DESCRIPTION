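Package: lfmbrain
Title: Whole-Brain Light Field Microscopy Functional Imaging Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fast near-whole-brain fluorescence imaging of
    behaving adult Drosophila with light field microscopy. Provides a seeded
    synthetic-data generator (atlas, sources, behavior, stimuli, rendered 4D
    movies), a toy light field forward model with Richardson-Lucy volumetric
    deconvolution and bead-based PSF characterization, the preprocessing chain
    (rigid motion correction, detrending, Kalman-style denoising, SVD artifact
    subtraction, dF/F, behavior alignment), PCA/ICA source extraction with
    singular-spectrum shoulder detection, atlas-based component annotation and
    artifact classification, and condition/stimulus brain-map statistics with
    indicator-kernel regressors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    tiff,
    png,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'atlas.R'
    'io.R'
    'lfmbrain-package.R'
    'lightfield.R'
    'mapstats.R'
    'methods.R'
    'pipeline.R'
    'preprocess.R'
    'sources.R'
    'synthgen.R'
    'utils.R'
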