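Package: sprintnet
Title: Correlation-Based Influence Networks for Sprint Running Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds correlation-thresholded influence networks from per-athlete
    physiological, anthropometric and biomechanical test outputs collected in
    free and tethered running, computes the node-importance metrics used in
    complex sports analytics (degree, power-method eigen-importance,
    betweenness centrality), simulates linear influence-state dynamics on the
    connection matrix, and aggregates the three metrics into a composite
    "performance node" ranking. Includes a Gaussian-copula synthetic athlete
    generator with quartile-matched marginals and planted correlation
    structure, so every pipeline stage is testable without access to raw
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    yaml
Suggests:
    igraph,
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
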