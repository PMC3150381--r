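Package: metacatch
Title: Metagenome-Style Diversity Profiling of Fishery Catches from DNA
    Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Treats all COI barcode sequences obtained from a multi-species
    fishery catch as a single pooled sample (a "fish metagenome") and profiles
    its diversity at three levels: genetic (pooled haplotype and nucleotide
    diversity, distinct polypeptides and the haplotypes-per-polypeptide
    ratio), ecological (Shannon index on sample composition, mean trophic
    level) and taxonomic (total taxonomic distinctness and total taxonomic
    path length over a six-rank Linnean tree). Includes dominant-species
    selection from catch statistics, proportional sample allocation,
    median-joining haplotype networks, neighbour-joining trees on COI protein
    distances with bootstrap support, and a synthetic multi-species barcode
    community generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
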