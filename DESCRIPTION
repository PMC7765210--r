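Package: loxfamily
Title: Genome Mining and Expression Analysis of Plant Lipoxygenase Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying and characterizing plant
    lipoxygenase (LOX) gene families from annotated genomes, modelled on the
    nine-member family of the greater duckweed Spirodela polyrhiza. Implements
    the bona-fide LOX decision rule (PLAT + complete LOX domain co-occurrence
    with a correctly spaced 38-residue 5-histidine signature), protein
    physicochemical properties (molecular weight, isoelectric point),
    subfamily classification (9-LOX vs 13-LOX, type I/II via a transit-peptide
    heuristic), exon/intron structure with intron phases, tandem and segmental
    duplication detection, neighbor-joining subfamily phylogenetics with
    bootstrap, and relative qPCR quantification (2^-ddCt) with one-way ANOVA
    and Dunnett multiple comparisons. Ships a deterministic synthetic-genome
    and qPCR-table generator with a ground-truth manifest so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
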