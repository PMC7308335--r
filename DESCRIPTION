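Package: vdjrss
Title: TCR-Beta Repertoire Architecture and Cryptic RSS/RUNX1 Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative profiling of T-cell receptor beta (TCRB) repertoires
    from paired-end amplicon reads: quality-weighted read-pair joining, V/J
    segment assignment, clonotype clustering with 1-bp/20-fold error merging and
    a 0.001% frequency cutoff, full CDR3 VDJ-architecture decomposition
    (segment truncations, N1/N2 insertions, D-segment calling with a 5-nt
    minimum, functionality), per-sample richness and ratio metrics, and
    between-group comparisons with two-tailed Mann-Whitney tests and
    median-based fold changes. A second arm scores cryptic recombination signal
    sequences (RSS): position weight matrices with an information-weighted
    similarity score, composite heptamer-spacer-nonamer module models (12+/-1
    and 23+/-1 bp spacers), stranded scanning, deletion-border window
    extraction, RUNX1-motif overlap counting and fold/Z-score/binomial
    enrichment statistics, spatial distance classification of RUNX1 hits, and
    ChIP-Seq peak RSS enrichment. Seeded simulators for repertoires, reads and
    motif-planted genomes make every stage testable without external data.
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
    purrr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
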