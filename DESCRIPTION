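Package: paternalRE
Title: Paternal Sperm RNA Element Contribution and Phthalate-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for defining the RNA elements (REs, exon-sized RNA
    fragments quantified in RPKM) that sperm deliver to the zygote at
    fertilization, and for intersecting them with phthalate
    (dibutyl-phthalate, DBP) responsive REs from a crossover-crossback
    exposure design. Implements the paternal/maternal decomposition of
    zygotic RE abundance with its capping rule, fivefold and twofold
    paternal-enrichment classifiers with sperm-specific calls, transcript
    integrity index (TII) sample QC with fourth-quartile exclusion,
    coverage-based full-length transcript calls, hypergeometric gene-list
    overlap statistics with representation factors and a normal
    approximation, p-value-stratified gene-set over-representation
    analysis with Benjamini-Hochberg FDR, movement-pattern classification
    across exposure segments, consistent-responder detection, CRREW
    (chromatin remodeler cofactor, RNA interactor, reader, eraser,
    writer) annotation, network-table export, and a fully seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
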