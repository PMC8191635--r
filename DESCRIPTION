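Package: m6ager
Title: Predicting N6-Methyladenosine Sites from Sequence Features and Graph
    Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies N6-methyladenosine (m6A) modification sites in RNA
    sequence segments. Implements seven sequence-derived feature encoders
    (CTD, PseKNC, NPS, NPPS, NCP-ND, EIIP, BPB), a sample-similarity network
    learned by the fast linear neighborhood similarity approach (FLNSA),
    three unsupervised graph embeddings of that network (modularity-spectrum
    SocDim, biased-random-walk Node2Vec, k-step transition-factorisation
    GraRep), and a class-weighted gradient-boosted decision-tree classifier,
    together with binary-classification evaluation (ACC, MCC, sensitivity,
    specificity, F1, ROC/AUC), a synthetic RRACH-motif benchmark generator,
    and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    igraph,
    irlba,
    jsonlite,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    RSpectra,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
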