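Package: layerprint
Title: Layer-Orthogonalized Stimulus Synthesis and Searchlight Mapping of
    Convolutional Network Layers onto the Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for representational similarity analysis (RSA) that map
    individual layers of a convolutional network onto the brain. Implements
    stimulus synthesis by gradient descent in pixel space so that the
    image-by-image representational similarity matrix (RSM) of every model
    layer is decorrelated from every other layer's, a model-adapter contract
    for exposing layer activations and input gradients of any convolutional
    network, constrained pseudo-random fMRI trial sequences with double-gamma
    HRF design matrices and mass-univariate GLM beta estimation, a synthetic
    fMRI generator embedding known layer geometries into voxel regions, cubic
    searchlight analyses of representational stability with subsampled nulls,
    leave-one-participant-out layer-to-brain regression with permutation-null
    z-scoring and a residual orthogonalization method, sign-flip max-statistic
    group inference, and layer-overlap statistics with bootstrap comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    RNifti,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
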