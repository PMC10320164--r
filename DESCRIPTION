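Package: resmine
Title: Resistance-Guided Prioritization of Fungal Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Target-directed (self-resistance-guided) genome mining for fungi.
    Builds reference sets of essential core genes with per-model duplication
    thresholds, functional classes, ubiquity, single-copy frequency and
    median pairwise Nei-Gojobori dN/dS; screens query genomes for duplicated
    core genes, core or resistance genes overlapping biosynthetic gene
    cluster (BGC) boundaries, and known resistance models via profile-HMM
    search; and reports prioritized BGCs as deterministic TSV tables for
    single- and multi-genome runs. Includes a deterministic synthetic-data
    generator (reference collections, ortholog tables, planted duplications
    and BGCs) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
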