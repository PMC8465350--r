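Package: mlgpop
Title: Multilocus Genotype Analysis for Clonal Fungal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of haploid multilocus genotype data
    (microsatellite/STR panels and multilocus sequence typing), aimed at
    clonal and partially sexual fungi. Provides genotype-table input and
    validation, collapsing of aligned sequences to haplotype alleles,
    multilocus genotype assignment and clonal correction, per-locus and
    per-population diversity statistics (allele counts, private alleles,
    gene diversity, polymorphism information content, genotypic diversity),
    distance-based AMOVA with PhiPT permutation tests, Nei's genetic
    distance, Mantel tests of isolation by distance, principal coordinates
    analysis, multilocus linkage-disequilibrium statistics (index of
    association and rBarD), pairwise phylogenetic compatibility tests,
    minimum-spanning-tree genotype networks, mating-type idiomorph
    summaries, and a synthetic-data generator with recorded ground truth
    for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere,
    igraph
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    Biostrings
Config/testthat/edition: 3
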