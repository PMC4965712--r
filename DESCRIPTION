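Package: dynppi
Title: Dynamic Protein-Protein Interaction Networks and Protein Complex
    Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs time-resolved weighted protein-protein interaction
    (PPI) networks by fusing a static interaction network with protein
    activity levels and windowed co-expression derived from time-course gene
    expression data, predicts protein complexes from each active subnetwork
    with a core-attachment clustering algorithm, filters highly overlapping
    candidates, and evaluates predictions against a benchmark complex
    catalogue with neighbourhood-affinity matching, precision/recall/F-score
    and clustering-wise Sn/PPV/Acc. Includes a deterministic synthetic-data
    generator with planted complexes for end-to-end validation, broom-style
    tidiers, ggplot2 autoplot methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
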