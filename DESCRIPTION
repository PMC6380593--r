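Package: synetr
Title: Synergistic Gene-Pair Networks for Cross-Study Survival Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers a data-driven network of synergistic gene pairs (SyNet)
    from survival-labelled gene-expression compendia spanning multiple
    studies, and evaluates network-guided outcome predictors under a strict
    leave-one-study-out cross-validation design. Gene pairs are scored by
    holdout AUC of a linear meta-gene, synergy relative to the best single
    gene, mean individual AUC and co-expression; the top pairs by a combined
    fitness form the network. Includes an overlapping group lasso and three
    classical network-based outcome predictors, degree-preserving network
    null models, overlap z-scores against shuffled networks, and
    graph-topological link prediction. A synthetic-data module generates
    multi-study compendia with planted marginal genes, synergistic pairs,
    correlated blocks, batch shifts and censored survival labels so the full
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    glmnet,
    igraph,
    jsonlite,
    limma,
    survival,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
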