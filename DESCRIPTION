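Package: effortr
Title: Reconstruction and Gridded Mapping of Global Fishing Fleet Capacity and Effort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs national fishing-fleet capacity time series from
    gappy observations (logistic growth fitting with disruption splitting,
    population-proxy scaling, and dedicated rules for unmotorized fleets),
    disaggregates fleets into vessel length classes and ISSCFG gear types with
    engine power and gross tonnage, converts capacity to nominal effort
    (kW x days at sea) and to effective effort via compounded technological
    creep from a 1949 baseline, and allocates national effort to a 0.5 degree
    global grid by prorating against mapped catch, with gear-family matching,
    constraint masks and Gaussian spreading. Includes a synthetic-world
    generator with known ground truth for end-to-end testing, and grid
    comparison statistics (cell-wise Spearman, V-measure with homogeneity and
    completeness, cosine similarity of latitudinal and longitudinal marginals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tidyr,
    tibble,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    readr,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
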