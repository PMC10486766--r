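Package: riceval
Title: Objective Evaluation of Cooked-Rice Eating Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An image- and texture-based pipeline for objective evaluation of
    cooked-rice eating quality in Geng (japonica) rice breeding. Scores cooked-rice
    appearance as the yellow-pixel percentage of an HSV hue-thresholded image,
    extracts texture-profile-analysis (TPA) descriptors (hardness, adhesiveness,
    springiness, cohesiveness, gumminess, chewiness, resilience) from
    double-compression force curves, decomposes sensory-panel scores into
    year/variety variance components with broad-sense heritability, performs
    best-subset linear model selection, and ships the published multi-variable
    prediction models for the integrated value of organoleptic evaluation (IVOE).
    Seeded generators produce synthetic rice images, force curves and panel score
    tables with known ground truth for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    broom,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
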