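Package: lncsieve
Title: Alignment-Free Coding-Potential Classification of Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes long noncoding RNAs from protein-coding
    transcripts, including partial-length (CDS-incomplete) transcripts
    typical of RNA-seq assembly, using eleven alignment-free sequence
    features: exon-level hexamer score, hexamer score distance and
    GC-content; length, score and score percentage of the maximum coding
    subsequence located by a Kadane-style maximum-subarray scan of
    in-frame hexamer log-ratio scores; and ORF length, coverage, Fickett
    TESTCODE statistic and ORF-level hexamer score and distance. An
    L2-regularized logistic regression with cross-validated
    regularization strength turns the features into a coding
    probability. Includes a synthetic transcript generator with known
    ground truth, confusion-matrix/ROC evaluation utilities, an
    accuracy-versus-cutoff sweep for operating-point selection, and a
    command-line interface with length-balanced parallel scheduling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
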