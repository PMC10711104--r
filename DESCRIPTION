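Package: acunet
Title: Stem and Leaf Segmentation and Phenotyping for Seedling Images
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semantic segmentation of seedling photographs into background,
    stem and leaf classes with an attention-augmented encoder-decoder
    network (VGG16 encoder, re-tuned atrous spatial pyramid pooling bridge,
    recurrent criss-cross attention on the decoder), trained with a
    composite Dice plus boundary (signed-distance) loss.  Includes
    receptive-field arithmetic and gridding-effect validation for dilated
    convolution schedules, pixel-level evaluation metrics (mPA, mIoU,
    precision, recall, F1), median-filter preprocessing, HSV/Otsu crown
    phenotyping, a seeded synthetic scene generator, and a command line
    interface covering the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
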