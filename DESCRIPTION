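Package: qsarscreen
Title: QSAR Regression Modelling and In Silico Screening with
    Genetic-Algorithm Descriptor Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and validates multiple linear regression (MLR)
    quantitative structure-activity relationship (QSAR) models for
    small-molecule activity data (pIC50).  Computes radial distribution
    function (RDF), Moran (MATS) and Geary (GATS) autocorrelation, and
    C-005 atom-centred fragment descriptors from 3D structures; prunes
    constant and collinear descriptors; splits compounds into training
    and prediction sets with the Kennard-Stone algorithm; selects
    descriptors by stepwise partial-F regression or by a genetic
    algorithm with leave-one-out cross-validation fitness; validates
    models internally (Q2, RMScv), externally (Golbraikh-Tropsha rules,
    rm2) and by Y-randomization; and screens candidate compounds inside
    a leverage-based applicability domain.  A synthetic-data generator
    with planted linear signal makes the whole pipeline testable
    without proprietary descriptor software.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
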