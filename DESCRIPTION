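Package: orimin
Title: Cell Cycle Phase Durations and Minimum Replication Origins for
    Single-Celled Eukaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the durations of the G1, S, G2, mitosis and
    cytokinesis phases of asynchronous exponentially growing single-celled
    populations from doubling time, phase fractions and EdU pulse-labeling
    observations, using the Williams (1971) and Stanners-Till (1960)
    equations.  Computes the minimum number of replication origins (MO)
    needed to duplicate each chromosome within the S phase given a mean
    replication-fork rate, including mild and harsh replication-stress
    scenarios, with exact integer arithmetic at the ceiling boundary.
    Converts DNA-combing inter-origin distances to per-chromosome origin
    counts, reads karyotypes from FASTA-index or TSV files (five reference
    karyotypes for Trypanosoma cruzi, Leishmania major, Trypanosoma brucei,
    Saccharomyces cerevisiae and Schizosaccharomyces pombe are bundled),
    fits origin-count-versus-chromosome-length trend lines per mapping
    method, and compares them against the MO threshold.  Includes a
    forward population simulator used as a round-trip oracle for the
    phase-duration estimator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
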