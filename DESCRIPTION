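Package: poreCNA
Title: Copy Number Inference and Run Kinetics for Short-Molecule Nanopore
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sparse read-depth copy-number analysis tailored to short-molecule
    nanopore sequencing runs. Implements run-kinetics quality control from
    sequencing-summary tables (cumulative yield, channel lifetimes, pore
    vacancy times, channel activity), variable-width genomic binning with
    GC normalization, circular binary segmentation with permutation
    significance and a five-bin transition rule, least-squares fitting of
    segment ratios to absolute integer copy numbers, read-count downsampling
    for resolution analysis, and Hamming-distance barcode demultiplexing for
    multiplexed runs. A synthetic-data generator emulates pore kinetics and
    copy-number read depth so every stage can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    Rsamtools,
    optparse,
    withr
Config/testthat/edition: 3
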