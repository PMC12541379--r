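Package: phagempr
Title: Proteome-Vector Representations for Phage Comparison and Hierarchy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents each bacteriophage proteome as a single mean vector of
    unit-normalized protein embeddings (a mean phage representation), compares
    proteomes by Euclidean distance, extracts a multi-scale hierarchy by
    density-based clustering with a minimum neighbourhood of two, and evaluates
    agreement with ICTV-style taxonomic annotations via adjusted mutual
    information and silhouette scores. Includes closed-form expectations for
    vector norms, dot products and distances under a protein-family mixture
    model, a von Mises-Fisher synthetic embedding generator with a nested
    taxonomy so the whole pipeline is testable without a protein language
    model, nearest-neighbour placement of new proteomes, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
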