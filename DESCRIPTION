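Package: smaddeconv
Title: De-Convolution of Smad2 Versus Smad3 Binding Sites from DNA Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies pooled Smad2/3 ChIP-seq peaks as Smad2- or
    Smad3-bound from 200-bp DNA sequence alone. Implements peak
    preprocessing (promoter filtering against transcription start sites,
    fixed-width resizing, sequence extraction), five-channel one-hot
    encoding, convolutional (CNN) and convolutional-recurrent (CNN-LSTM)
    classifiers trained as snapshot ensembles under a cosine-annealing
    learning-rate schedule with warm restarts, precision-recall based
    evaluation for the imbalanced two-class problem, an ensemble-size
    ablation, a nearest-peak concordance diagnostic, and a synthetic
    sequence generator with planted Smad-binding-element and co-factor
    motifs for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
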