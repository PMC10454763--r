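Package: strainsig
Title: Strain-Level Metagenomic Profiling with n-Gram Signature Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds body-site-specific DNA signature element models (DSEMs)
    from sets of reference genomes by indexing every distinct fixed-length
    n-gram (k-mer) together with the genomes that contain it, weighting each
    n-gram by an inverse-document-frequency-style score that rewards
    discriminatory sequence. Metagenomic read sets are identified against a
    model by accumulating weighted n-gram matches per genome, with a presence
    cutoff calibrated empirically from positive and negative score
    distributions, and relative abundances are estimated by per-read
    assignment using unique and weighted common n-grams. Includes a read and
    community simulator for mock-community benchmarking and standard
    sensitivity/specificity/F1 evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
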