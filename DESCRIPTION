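Package: dnnmapr
Title: Mapping Artificial Neural Network Representations onto Neural Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A toolbox for relating the internal representations of artificial
    neural networks to measured neural responses. Extracts layer activations
    of a network for a stimulus set through a mask of layers, channels and
    units; fits cross-validated linear encoding models (GLM, ridge, lasso,
    partial least squares) from network features to site-wise responses and
    decoding models in the reverse direction, with permutation inference;
    compares representational geometries via representational dissimilarity
    matrices; and characterizes single units by top-stimulus ranking,
    gradient saliency maps, occlusion receptive fields, channel ablation and
    optimal-stimulus synthesis. Ships deterministic toy fixture networks and
    synthetic stimulus/response generators with known ground truth, plus a
    command-line interface over CSV/HDF5 file formats.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    mixOmics,
    png,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
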