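Package: nucsig
Title: Sequence-Based Prediction of H3K4me3 and H3 Nucleosome Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates state-specific k-mer sequence specificities of
    H3K4me3-modified and unmodified H3 nucleosomes from ChIP-seq read
    positions, and uses them as fifth-order emission models in a hidden
    Markov model over competing nucleosome arrangements to compute, for
    every base pair of a genome, the posterior probability of being covered
    by an H3K4me3 nucleosome, an H3 nucleosome, or no nucleosome.  Includes
    positional dinucleotide periodicity profiles, Poisson enrichment
    calling, precision-recall evaluation of occupancy tracks, and a
    synthetic-data generator that simulates genomes and ChIP-seq-like reads
    from planted nucleosome arrangements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
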