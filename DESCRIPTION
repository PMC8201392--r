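Package: retfuse
Title: Adversarial Attacks and Defenses for Retinal Fundus Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the adversarial robustness of diabetic-retinopathy
    image classifiers at desk scale. Generates seeded synthetic fundus-like
    images in three severity grades, trains a compact convolutional surrogate
    classifier with exact input gradients, crafts fast-gradient-sign (FGSM),
    multiplicative speckle-noise and DeepFool adversarial images, and
    evaluates two defenses: adversarial-training regimes (single-attack and
    mixed) with cross-testing matrices, and serial fusion of deep
    global-average-pool features with handcrafted LBP, HOG and SFTA texture
    descriptors classified by SVM, cubic-distance k-NN or a bagged-tree
    ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    png,
    EBImage,
    e1071,
    randomForest,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
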