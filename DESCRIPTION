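Package: cardioniche
Title: Cellular Niche Discovery, Drug-Target Scoring and Enrichment
    Statistics for Cardiac Single-Cell and Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for linking cell states of the heart to
    drugs, tissue microenvironments and genetic traits. Provides drug-target
    scoring of single cells from ChEMBL-style drug-target tables with
    family-specific bioactivity cutoffs and ATC grouping; gene-set scoring
    with expression-binned control genes; rank-sum drug ranking per cell
    state; knowledge-based spatial enrichment (odds ratios and chi-square)
    of deconvolved cell-state abundances in annotated structures; a
    product-abundance niche caller; unsupervised microenvironment discovery
    by non-negative matrix factorization with permutation-based best-factor
    and fine-factor selection; GWAS SNP enrichment in cell-state open
    chromatin with a label-shuffling permutation null; and a ligand-receptor
    interaction screen over CellPhoneDB-style interaction and complex
    tables. Seeded synthetic-data generators emulate every input format with
    planted signal so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
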