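Package: TumorWaveNet
Title: Wavelet Denoising, Hybrid Wave Metaheuristic Feature Selection and
    Dense Convolutional Classification for Brain Tumor MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for classifying brain tumors
    in T1-weighted contrast-enhanced MRI slices. Provides spatially selective
    wavelet denoising driven by a hierarchical inter-scale correlation map, a
    shallow U-Net autoencoder for feature extraction with the associated
    pixel-wise soft-max, border-weight-map and weighted cross-entropy
    operators, a hybrid water-wave/whale metaheuristic (HybWWoA) wrapped for
    binary feature selection, a configurable DenseNet classification head,
    confusion-matrix metrics with record- and subject-wise cross-validation
    planning, readers for the public cjdata brain-tumor HDF5 dialect, and
    seeded synthetic generators (phantom images, labeled feature matrices,
    noisy piecewise-constant signals) so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    EBImage,
    rhdf5,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, FeatureExtraction, Preprocessing
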