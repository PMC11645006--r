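Package: canopy3d
Title: Plant Stress Detection from Single Top-View RGB Images via 3D Leaf
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Ana", "Quiroga", email = "ana.quiroga@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting water and nutrient stress in potted crops from
    a single top-view RGB image. The pipeline trains a 32x32-patch
    convolutional classifier and runs it as a sliding window for plant/no-plant
    semantic segmentation, gates SLIC superpixels on segmentation purity to
    isolate leaf regions, regresses an 8-bit depth code per patch to obtain a
    dense depth map, back-projects leaf pixels through the pinhole camera model
    into metric point clouds, summarises each leaf by its moment centroid, and
    classifies stress with a 15-128-64-32-64-128-2 feed-forward network. A
    seeded synthetic plant-bed generator emulates paired RGB/depth records with
    eight irrigation groups, and the evaluation module provides confusion
    metrics, AUC, the Polygon Area Metric, k-fold cross-validation, method
    comparison deltas, and the moisture-ratio drying utility.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
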