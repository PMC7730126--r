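Package: morphoscreen
Title: Analysis of Combinatorial 3D-Microenvironment Morphogenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for high-content screens of epithelial
    morphogenesis in combinatorial synthetic-hydrogel microenvironments.
    Enumerates full-factorial screen designs (matrix stiffness, protease
    degradability, ECM protein combinations, soluble EGF), segments colonies
    in whole-well images, computes a 102-measurement morphometric profile
    per colony (area-shape, intensity/radial, and co-occurrence texture
    families), classifies colonies into four morphogenetic phenotypes with
    an iteratively validated random forest, and analyses the resulting
    per-well phenotype frequency profiles by singular value decomposition,
    binomial generalized linear models with stepwise AIC selection and
    Tukey-Kramer contrasts, and top-fraction ranked condition maps. A
    seeded synthetic-plate generator renders the four actin architectures
    with planted condition effects so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    MASS,
    car,
    emmeans,
    randomForest,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
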