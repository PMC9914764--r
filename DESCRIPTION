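Package: shelfrsm
Title: Response-Surface Shelf-Life Modelling for Packaged Oyster Mushrooms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling the shelf-life of fresh Pleurotus ostreatus
    mushrooms grown on agro-industrial residue substrates and stored under
    different packaging types and temperatures. Implements the replicated
    3x3 designed experiment (packaging type by residue incorporation rate),
    second-order polynomial response-surface fitting by least squares, the
    full model-adequacy toolkit (partial-F ANOVA, lack-of-fit versus pure
    error, PRESS and predicted R-squared, adequate precision), analytic
    maximisation of the fitted surface over the admissible factor box with a
    Derringer desirability layer, classification of total microbial counts
    (log10 CFU/g) into contamination bands with consumability windows, and
    physicochemical quality metrics (weight loss, veil opening,
    acceptability rules). A synthetic-data generator reproduces the
    statistical structure of each data type for testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
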