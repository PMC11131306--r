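Package: paleolocus
Title: Joint Analysis of Archaic and Modern Human Variation at a Gene Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint population-genetic analysis of a gene locus in
    archaic (Neanderthal, Denisovan) and modern human genomes: merging phased
    modern haplotypes with archaic diploid genotypes from VCF, identity-by-state
    distances and weighted multidimensional scaling, ordinal SMACOF ordination of
    population selection statistics, a lineage-specific derived-allele
    conservation resampling test against per-base phyloP-style scores, archaic
    introgression summaries from Sprime-style tables and introgression maps,
    empirical standardization of windowed selection statistics (nucleotide
    diversity, Fay and Wu's H), screening of archaic missense variants, and a
    synthetic-data generator emulating all required input formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
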