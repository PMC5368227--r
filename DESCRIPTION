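Package: primerscout
Title: In Silico Evaluation of Degenerate 16S rRNA Gene Primers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate degenerate PCR primers against
    taxonomy-annotated rRNA reference databases. Locates the best binding
    site of each IUPAC primer on every reference sequence with a
    3'-weighted mismatch/gap score, aggregates hits into per-taxon
    coverage, non-coverage and terminal-base mismatch tables, predicts
    amplicons for primer pairs and summarises amplicon length
    distributions, and generates synthetic taxonomy-annotated reference
    sets with planted primer-site defects so the whole pipeline can be
    validated against exact ground truth. Includes qPCR standard-curve
    efficiency helpers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
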