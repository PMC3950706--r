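Package: peakconcord
Title: Concordance Analysis of ChIP-Seq Occupancy Across Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing protein-DNA occupancy between ChIP-Seq
    datasets: duplicate-read capping and censoring of over-amplified start
    positions, a Poisson sliding-window enrichment caller with sample-swap
    empirical FDR, control-based peak exclusion, merging of FDR-selected
    peak sets across datasets with fold-tolerance Venn partitioning,
    summit detection by read elongation and pileup, TSS-proximal peak
    annotation and metaprofiles, cross-species bound-gene comparison via
    one-to-one orthologs, and Fisher's exact gene-set enrichment with
    Benjamini-Hochberg correction. Includes a seeded synthetic-data
    generator with truth tables so every stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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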