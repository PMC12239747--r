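Package: tbysim
Title: Simulation and Decoding of TILLING-by-Sequencing Pooled Mutation Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and decoding TILLING-by-Sequencing
    (TbyS) reverse-genetics screens of EMS-mutagenized plant populations.
    Implements the bidimensional (horizontal x vertical) DNA pooling design used
    to screen 96-well plates of M2 families, a generator for synthetic
    EMS-mutagenized populations with the canonical G:C->A:T substitution
    spectrum and selfing-derived zygosity, a binomial model of pooled target
    sequencing with allele-frequency based variant detection, demultiplexing of
    pool-level variant calls back to unique plate wells, codon-level
    classification of induced SNPs (missense, nonsense, silent), and the
    family- and screen-level summary tables used to report such screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
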