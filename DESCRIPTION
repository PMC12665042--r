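Package: snapmeta
Title: Deep Metagenomic Snapshot Profiling of Complex Environmental Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting multiple genomic resources from a single deep
    shotgun-metagenomic sequencing run of a complex environmental sample, such
    as the fermented pollen-nectar larval food of stingless bees. Implements
    weighted-score representativeness ranking of BLAST subjects for reference
    genome selection (the Species Match score), best-hit taxonomic profiling
    with E-value filtering, a reference-guided majority-vote consensus caller,
    assembly quality metrics over ambiguous-base runs, pollen count-table
    diversity statistics (Shannon-Wiener H', Pielou's J), and ANI/dDDH
    threshold-based species delineation. A synthetic-community simulator
    generates genomes, mutated strains, read sets, abundance-structured hit
    tables, gapped assemblies and multinomial pollen counts with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
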