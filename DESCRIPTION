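Package: pfdist
Title: Nonlinear Chordal Distance Measures for Pythagorean Fuzzy Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Distance measures and decision-support pipelines for Pythagorean
    and intuitionistic fuzzy sets. Implements two nonlinear distances built
    on the chordal (stereographic) metric and on a non-Archimedean
    valuation kernel, together with a registry of sixteen established
    distance measures whose published numerical tables were computed under
    mixed evaluation dialects; per-table replication conventions make every
    dialect reproducible. Includes nearest-prototype classification,
    ideal-solution ranking of alternatives over benefit and cost criteria,
    parameter sensitivity sweeps with rank-stability flags, and a
    discrimination diagnostic that detects measures assigning identical
    distances to distinct profile pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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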