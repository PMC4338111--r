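Package: pathora
Title: Pathway Diagrams, Omics Data Overlay and Over-Representation Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Read, write, validate and render biological pathway diagrams in
    the GPML (Graphical Pathway Markup Language) format; import tabular omics
    data and map its identifiers onto pathway data nodes through a
    table-driven cross-reference mapper; select genes of interest with a
    boolean criterion expression language with three-valued missing-data
    semantics; score each pathway in a collection with the hypergeometric
    Z-score used in over-representation analysis and rank the results; and
    paint gradient- or rule-based colors for each data column into the data
    node boxes of an SVG rendering of the diagram.  A synthetic fixture
    generator builds pathway collections, mapping tables and datasets with a
    planted enriched pathway for testing and demonstration, and a small
    command-line interface exposes the main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
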