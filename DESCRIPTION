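Package: lncfun
Title: Predicting lncRNA Gene Ontology Functions from Heterogeneous Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology (GO) functions for long non-coding RNAs
    by embedding a global lncRNA-protein-miRNA heterogeneous network and
    transferring annotations from proteins. The network is assembled from six
    component similarity/association networks, diffused by random walk with
    restart, re-weighted as a positive pointwise mutual information (PPMI)
    matrix, and compressed with a stacked denoising autoencoder; per-GO-term
    support vector machines trained on protein embeddings then score lncRNAs,
    and predictions are evaluated with the CAFA-style Fmax protocol. Includes
    a seeded synthetic-network generator with planted functional modules so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
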