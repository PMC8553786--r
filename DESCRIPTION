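Package: methinherit
Title: Differential DNA Methylation, Paternal Inheritance and Embryonic
    Reprogramming Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing paternal epigenetic inheritance from
    replicated whole-genome bisulfite sequencing count data. Calls
    differentially methylated cytosines and regions between two groups
    with a smoothed, dispersion-shrunk beta-binomial Wald test;
    classifies regions as intergenerationally or transgenerationally
    inherited across three sperm generations; classifies the erasure and
    reestablishment dynamics of regions across embryonic stages (inner
    cell mass, primitive streak, primordial germ cells) relative to
    paternal sperm, including escape analysis for imprinted genes,
    transposable elements and variably methylated IAPs; tests
    differential enrichment of annotated sperm small non-coding RNAs and
    matches differential sequences to region sequences with a seed-window
    aligner. A synthetic-data generator with planted effects allows every
    stage to be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
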