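Package: cysbond
Title: Disulfide Connectivity Prediction from Phylogenetic Tandem Cysteine Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised prediction of disulfide bond connectivity for a
    protein with known cysteine oxidation states. Homologous sequences from a
    multiple sequence alignment are filtered to even cysteine parity, placed on
    a neighbor-joining tree rooted with a shuffled-query outgroup, and labeled
    with ancestral cysteine-presence states under a loss-only parsimony model.
    Tandem (compensatory) cysteine losses observed between adjacent tree nodes
    accumulate as edge weights of a connectivity graph that is resolved into a
    bonding pattern by exact maximum-weight perfect matching. Includes Rb/Qp
    evaluation metrics with closed-form random baselines, a family simulator
    with planted connectivity for end-to-end validation, and the 523-dimension
    cysteine-pair feature encoder used by supervised benchmark predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phytools,
    seqinr,
    Rcpp,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
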