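Package: pirnaprofiler
Title: Transposon piRNA Profiling from Small-RNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reproducible pipeline for profiling PIWI-interacting
    RNAs (piRNAs) in small-RNA sequencing libraries: 3' adapter
    identification and removal with a mismatch tolerance, retention of
    23-30 nt inserts, zero-mismatch strand-aware mapping to a genome and a
    transposon consensus set, reads-per-million (RPM) normalisation against
    perfect genome-mapping reads, 5'-uridine (1U) and antisense strand bias
    statistics, and mutant-versus-wild-type relative-expression
    classification with replicate summaries. Ships a synthetic small-RNA
    library generator with per-read ground truth so every stage of the
    analysis is testable without access to deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
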