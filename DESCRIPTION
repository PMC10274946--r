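Package: prfscan
Title: Prediction of Programmed Ribosomal Frameshift Sites in Prokaryotic and Viral Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies programmed ribosomal frameshift (PRF)
    sites in annotated prokaryotic and viral genomes. Joined CDS features in
    GenBank flat files are used to derive training labels; candidate slippery
    sites inside gene-overlap regions are scored with eleven cellular
    properties (frameshift direction, slippery-motif class, A-site codon
    usage in the original and shifted frames, two Shine-Dalgarno ribosome
    binding site scores, four normalized minimum-free-energy windows of
    downstream RNA structure, and the distance to the in-frame stop codon)
    and classified as backward (-1), forward (+1), or non-frameshift with a
    gradient-boosted tree model. Includes MinHash genome sketching for
    identity-based grouping in leave-one-group-out validation and a
    synthetic-genome generator that plants frameshift signals for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    xgboost,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
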