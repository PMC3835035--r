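Package: projectin
Title: In Silico Characterization of Projectin-Like Giant Muscle Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-scale characterization of projectin-like giant
    muscle-protein genes: greedy overlap assembly of genomic fragments with
    misassembly and gap reporting, detection of PEVK compositional-bias
    segments in proteins and three-frame translations, homology-guided
    exon-intron prediction with canonical GT-AG splice-site refinement and
    cDNA verification, mapping of the canonical Ig/Fn/kinase domain
    architecture, enumeration of PEVK alternative-splicing isoforms with
    in silico RT-PCR amplicon prediction per muscle type, cross-species
    summary statistics, and a fully seeded synthetic-data generator that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
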