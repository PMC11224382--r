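Package: freshfuse
Title: RGB-Hyperspectral Fusion for Vegetable Soybean Freshness Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grades the freshness of vegetable soybean pods (storage day 1, 3,
    5 or 7) from paired RGB images and 462-band mean reflectance spectra.
    Implements the full pipeline: multiplicative scatter correction and
    first-derivative spectral preprocessing, crop/box-downsampling of pod
    images to 22x21 pixels, fusion of the reshaped spectrum with the RGB
    tensor into a 22x21x4 input, a small residual convolutional network
    classifier trained with Adam, four classical machine-learning baselines,
    distance-correlation band selection with zero-ablation, macro
    classification metrics with Wilson score intervals, and a synthetic
    paired-data generator so every stage is testable without the original
    imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, grDevices, graphics, utils, jsonlite, png, rpart, randomForest, class
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
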