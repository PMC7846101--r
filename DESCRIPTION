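Package: httrace
Title: Detection and Dating of Horizontal Transposon Transfer from Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering horizontal transposon transfer (HTT) of
    LINE retrotransposons from genome assemblies: curation of repeat
    consensus sequences by iterative search-extend-align-trim refinement,
    presence/absence screening of families across genome and transcriptome
    panels, coverage and divergence profiling of copies against their
    consensus, insertion-age estimation from substitution rates,
    gain-parsimony inference of transfer events on dated host phylogenies,
    repeat-versus-species tree discordance statistics, and gene-context
    annotation of insertions with flank-contiguity validation. Includes a
    synthetic-genome simulator of vertical and horizontal transposable
    element histories used as the ground-truth test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
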