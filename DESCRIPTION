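Package: mixmm
Title: Mixture of Multinomial Mixture Models for Mutational Signature
    Discovery from Sparse Mutation Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous soft clustering of tumour samples and estimation of
    mutational signatures and per-cluster exposures from sparse SBS-96
    mutation count catalogs, as produced by targeted gene-panel sequencing.
    Implements a mixture of multinomial mixture models trained by
    expectation-maximization with multi-restart initialisation, de-novo and
    signature-refitting modes, BIC model selection over the number of
    clusters and signatures, hard- and soft-clustering exposure inference,
    a generative simulator with Poisson and panel-region downsampling, and
    evaluation utilities (NNLS refitting baseline, reconstruction errors,
    cosine signature matching, adjusted mutual information).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
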