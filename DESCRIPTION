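Package: u12retain
Title: Minor-Spliceosome Intron Classification and Retention Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for studying minor (U12-type) intron splicing defects in
    two-condition transcriptome experiments, motivated by mouse embryos
    mutant for the Zrsr1/Zrsr2 splicing factors. Extracts strand-aware intron
    catalogs from a genome and annotation, classifies introns as U2 or U12
    (AT-AC / GT-AG subtypes) with position weight matrices for donor, branch
    and acceptor sites, quantifies alternative-splicing events by percent
    spliced-in (PSI) and calls differential events by delta-PSI, tests U12
    enrichment among retained introns and the adjacency of affected U2
    introns to U12 introns, models imprinting/X-inactivation-dependent
    offspring viability for Zrsr1 x Zrsr2 crosses, and provides
    comparative-CT qPCR fold changes. A seeded synthetic-data generator
    produces genomes, annotations, count tables and crosses with known
    ground truth so every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    ggplot2,
    generics,
    rlang,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
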