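Package: lesionmap
Title: Mapping Quantitative CT Lesion Features to Visual Semantic Terms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a 496-dimensional quantitative feature vector from a
    2-D CT slice and a lesion region of interest (intensity, texture, shape,
    histogram and edge blocks plus a lesion-multiplicity count), detects and
    counts satellite lesions that resemble the primary lesion via weighted
    within-class-variance thresholding and an (alpha, beta) similarity
    signature, and learns per-term feature subsets for visual semantic term
    (VST) prediction by mutual-information-ranked forward selection gated on
    fivefold cross-validated SVM accuracy.  Includes seeded phantom
    generators so the whole pipeline is testable without clinical data,
    broom-style tidiers and ggplot2 autoplot methods for every result type,
    and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    igraph,
    jsonlite,
    withr,
    EBImage,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
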