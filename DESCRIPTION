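Package: ednet
Title: Compact Convolutional Networks for Seven-Class Eye-Disease Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds, analyses and trains ED-Net, a compact convolutional
    neural network for classifying eye images into seven disease categories
    (bulging eyes, cataracts, crossed eyes, diabetic retinopathy, glaucoma,
    uveitis, normal). Provides the swish6 clipped-swish activation and pooling
    primitives, declarative layer and block specifications assembled into the
    full network, an exact parameter and multiply-accumulate complexity
    counter with a VGG16 validation fixture, a deterministic synthetic
    eye-image generator emulating the published class imbalance, and a
    from-scratch SGD training loop with momentum, weight decay and
    exponential learning-rate decay. All numerics are plain R arrays; no
    deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
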