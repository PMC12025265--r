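Package: bmdnet
Title: Bone Mineral Density Estimation from Radiographs via Learned
    Soft-Tissue Subtraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A hybrid pipeline for estimating lumbar bone mineral density
    (BMD, g/cm^2) from single-energy anteroposterior radiographs. Synthetic
    phantom radiographs with known soft-tissue/bone decomposition and known
    density are generated for training; a U-Net, implemented and trained from
    scratch with plain stochastic gradient descent, predicts the soft-tissue
    component which is subtracted to leave a bone-dominant image; the vertebral
    region of interest is partitioned into five named regions whose
    threshold-clipped grayscale means, together with body weight and vertebral
    area, form a 23-element feature vector; a small feed-forward network with a
    bounded tanh output activation maps features to BMD. Includes evaluation
    utilities (Pearson r, R^2, MAE) and a paired comparison of the pipeline
    with and without soft-tissue subtraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
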