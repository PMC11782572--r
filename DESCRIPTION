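Package: exonscan
Title: Exon Detection from Three-Base Periodicity with an Optimized
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects protein-coding regions (exons) in eukaryotic DNA from
    their three-base periodicity. DNA is mapped to four binary indicator
    tracks (Voss representation), a period-3 spectral-energy profile is
    computed with a modified Gabor wavelet transform (with a short-time
    discrete Fourier transform baseline), profiles are framed into 16x16
    images, and a small convolutional network classifies frames as exonic
    or intronic. The network's layer structure and hyperparameters are
    found by an African Vulture Optimization Algorithm minimizing the bit
    error rate. Includes a synthetic-genome generator with tunable codon
    bias so the whole pipeline is testable without external data, plus
    confusion-matrix, ROC and threshold-sweep reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    pROC,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
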