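Package: habscape
Title: Habitat Quality and Landscape-Pattern Dynamics on Categorical Rasters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated land-change and habitat-quality workflow for
    semi-arid watershed landscapes. Generates seeded synthetic seven-class
    land-cover maps with controllable clumping, derives binary threat layers
    (agriculture, livestock grazing, urban, rural, mining, roads), computes
    an InVEST-style habitat-quality surface from distance-decaying threat
    kernels with a half-saturation transform, estimates Markov transition
    matrices between dated maps and projects future land cover by
    suitability-ranked allocation, computes landscape-level pattern metrics
    (number of patches, patch density, Shannon diversity, contagion), and
    relates habitat quality to those metrics by tile-wise Pearson
    correlation. Includes classification-accuracy statistics (overall
    accuracy, Cohen's kappa, Cramer's V) and NDVI-based rangeland condition
    classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
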