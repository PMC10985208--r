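Package: mircnn
Title: Plant miRNA Discovery from Small RNA-Seq with a Convolutional
    Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying plant microRNA
    (miRNA) loci from small RNA sequencing reads mapped to a genome.
    Reads are collapsed and length-filtered (20-24 nt), exact-matched to
    both genome strands, and clustered into candidate loci; precursor
    windows are excised around each cluster, folded with a base-pair
    maximisation (Nussinov) dynamic program, and screened for
    single-stem hairpins. Candidates are labelled by Meyers-style
    miRNA/miRNA* duplex criteria, encoded as 7 x L matrices combining
    one-hot sequence, pairing state and normalised read coverage, and
    classified by a small convolutional neural network (two 2x2
    convolution + max-pooling blocks, a 500-unit fully connected layer
    and a softmax output) trained with AdaDelta, dropout and minority
    oversampling under stratified k-fold cross-validation. A seeded
    synthetic-data module generates toy genomes with planted miRNA and
    siRNA-like loci for testing every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
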