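Package: ringmapr
Title: Single-Molecule Correlated Chemical Probing (RING-MaP) Analysis for Long RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects statistically significant co-occurring chemical
    modifications (RNA interaction groups, RINGs) between nucleotide pairs
    on single molecules from mutational-profiling (MaP) sequencing reads of
    long, randomly primed RNAs. Per-read mutation records are streamed into
    an upper-triangular store of 2x2 contingency tables; pairs are tested
    with the Yates continuity-corrected chi-squared statistic and scored
    with the signed phi coefficient. Replicates are merged by intersection,
    and the resulting weighted correlation network is filtered (edge
    strength, k-core) and partitioned into structural communities by
    Louvain modularity maximization. Also provides per-nucleotide
    mutation-rate reactivity profiles with differential footprint calling,
    and a randomly primed paired-end read simulator with analytic
    correlation oracles so the whole pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
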