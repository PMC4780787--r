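Package: qcfnet
Title: Phylogenetic Network Inference from Quartet Concordance Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-pseudolikelihood estimation of level-1, semi-directed
    phylogenetic networks (topology, branch lengths in coalescent units and
    inheritance probabilities) from quartet concordance factors, under the
    multispecies coalescent model extended with hybridization. Includes exact
    expected quartet concordance factors on level-1 networks via closed forms
    and a coalescent-history enumeration engine, concordance-factor estimation
    from gene-tree collections with missing taxa and support filtering, a
    gene-tree simulator under the network coalescent, heuristic search over
    network space with identifiability-aware parameterization, bootstrap
    support summaries and slope-heuristic selection of the number of
    hybridizations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    minqa,
    Rcpp,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
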