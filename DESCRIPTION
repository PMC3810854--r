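Package: covmod
Title: Covariance Models for RNA Homology Search and Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build covariance models (profile stochastic context-free
    grammars) of RNA families from structure-annotated multiple sequence
    alignments, calibrate E-value statistics by simulated search against
    random sequence, and search nucleotide databases with a staged
    profile-HMM filter pipeline followed by HMM-banded CYK and Inside
    scoring. Includes Stockholm/FASTA input and output, a model text
    format, structural alignment of sequences to a model, and a synthetic
    benchmark generator with pseudo-genome embedding and ROC-style
    scoring of ranked hit lists.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
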