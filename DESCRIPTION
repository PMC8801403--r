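Package: geis
Title: Design and Analysis of Gene Editing Through an Intronic Selection Marker
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the GEIS strategy (Gene Editing through an Intronic
    Selection marker), a homology-directed-repair knock-in design in which the
    selection cassette is placed in an intron while the desired variants ride on
    a homology arm. Provides genome-wide editability statistics from GFF3
    annotation (exon length distributions, UTR-excluded, under a conversion
    tract budget), splice-safe intronic sgRNA enumeration and donor assembly
    with variants at defined distances from the cut, amplicon-based calling of
    variant incorporation from Sanger-scale reads, conversion-tract statistics
    (per-distance conversion frequency, conditional co-occurrence, clone
    recombination rates), a maximum-likelihood geometric conversion-tract-length
    model, and a synthetic-data generator emulating the whole experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
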