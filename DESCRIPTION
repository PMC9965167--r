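Package: maizefuse
Title: Multimodal UAV Data Fusion and Multi-Task Learning for Maize Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for plot-level maize phenotyping
    from co-registered UAV hyperspectral, LiDAR and thermal imagery. Provides a
    synthetic field-trial generator with nitrogen treatment blocks, LiDAR point
    cloud rasterization (DSM/DTM/CHM and intensity surfaces), k-means++
    vegetation segmentation of plot chips, exhaustive extended normalized
    difference spectral index (NDSI) band-pair screening, a 95-feature
    vegetation index library, support vector and random forest regression
    baselines with nested grid search and impurity importance, a multimodal
    multi-task convolutional network with aligned random-crop augmentation and
    Huber loss, and spatially aware evaluation of trait predictions including
    Global Moran's I residual analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    MASS,
    FNN,
    interp,
    e1071,
    ranger,
    jsonlite,
    yaml,
    ggplot2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
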