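Package: nagnag
Title: Detection and Prediction of NAGNAG Tandem Acceptor Alternative
    Splicing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies NAGNAG tandem 3' splice acceptors (two AG
    dinucleotides three nucleotides apart) at annotated intron-exon
    boundaries, adjudicates the splicing outcome at each site (exonic E,
    intronic I, or alternative EI) from spliced transcript alignments under
    quality and junction-support filters, extracts a 31-feature sequence
    representation of the acceptor neighbourhood (positional nucleotides,
    polypyrimidine-tract Y-content, and position-weight-matrix acceptor
    strength scores), and fits a three-class naive Bayes classifier that
    predicts the splicing outcome from sequence alone, with stratified
    cross-validation, one-vs-rest ROC/AUC, and information-gain feature
    ranking. A synthetic-data module generates toy genomes, annotations and
    spliced alignments with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
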