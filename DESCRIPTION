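Package: mitocircle
Title: Plant Mitochondrial Master-Circle Finishing, Recombination
    Conformations and RNA-Editing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for finishing plant mitochondrial genome assemblies into a
    master circle and analysing their dynamic structure. Includes a synthetic
    genome and read simulator (circular mtDNA with inverted/direct repeat
    pairs, plastid-derived insertions, multi-exon genes and C-to-U editing
    sites), chloroplast read subtraction and mitochondrial read recruitment,
    contig-graph construction with repeat anchoring validation and master
    circle selection, enumeration of repeat-mediated recombination
    conformations, annotation screens (pseudogene classification, plastid
    insertion and repeat detection, ORF inventory, category accounting), and
    RNA-seq based detection of C-to-U editing sites with editing levels and
    codon effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
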