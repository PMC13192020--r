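Package: satkit
Title: Satellite DNA Annotation, Divergence, Transcription and Age Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for satellitome analysis on genome assemblies: annotation of
    satellite DNA monomers and arrays from family consensus sequences at up to 45
    percent divergence, Kimura 2-parameter divergence landscapes with 1 percent bins
    and rule-based peak calling, array flank extraction and conservation profiling,
    quantification of satellite transcription from RNA-seq reads against head-to-tail
    dimer references with FPKM normalisation, neighbor-joining monomer phylogenies
    with bootstrap supports, and minimal-age estimation of satellite families from
    taxonomic presence on a time-calibrated tree. Includes simulators for synthetic
    genomes with planted arrays, stage- and sex-structured read sets, and presence
    matrices with known truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    ape,
    graphics,
    jsonlite,
    methods,
    tools,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
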