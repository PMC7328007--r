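Package: platepheno
Title: Automated Segmentation and Colour Classification of Yeast Colonies on Agar Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline for quantifying red/white colony colour
    phenotypes in adenine-auxotrophy assays. A small encoder-decoder
    convolutional network segments colonies from plate photographs, connected
    regions are filtered by eccentricity and area, single-colony crops are
    classified into five phenotype classes (white, red, pink, variegating,
    bad segmentation) by a convolutional classifier with test-time
    augmentation, and predictions are aggregated into per-plate non-white
    percentages. Includes a synthetic plate generator with pixel-exact ground
    truth so both trainable stages can be trained and evaluated without
    external data, cyclical (circular and cosine-annealing SGDR) learning-rate
    schedules, and evaluation reports with confusion matrices and pooled
    white/non-white accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
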