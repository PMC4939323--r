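Package: enhsnp
Title: Identify Disease-Related Enhancer SNPs from GWAS and Histone ChIP-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for prioritizing disease-associated regulatory variants
    located in enhancer elements. Lead SNPs from a GWAS catalog are filtered by
    association p-value, expanded through pairwise linkage-disequilibrium (r2)
    records to a candidate set, and intersected with enhancer regions called
    from paired H3K4me1/H3K4me3 ChIP-seq coverage by a log2 signal-ratio
    threshold. Hits are validated against a regulatory-variant annotation
    table with distal target-gene links. Includes a seeded read simulator
    with planted enhancer intervals for end-to-end testing, and packaged
    reference tables for a liver-cancer (HepG2) use case.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
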