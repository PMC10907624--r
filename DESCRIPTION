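Package: combnet
Title: Patient-Oriented Combination Therapy Design from Ex Vivo Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs candidate drug combinations from ex vivo drug-response
    screens of patient and healthy-donor samples. Builds a weighted
    sample-drug bipartite network from normalized inhibition rates, projects
    it onto the drug side to obtain a drug similarity network, detects drug
    communities by weighted Louvain modularity maximization, and corroborates
    the clustering with protein-target preference scores, hypergeometric
    enrichment, and Dice similarity of chemical fingerprints. Candidate drugs
    are ranked by efficacy (mean inhibition on patient samples) against
    toxicity (mean inhibition on healthy samples), inter-cluster pairs are
    evaluated with reimplemented HSA, Bliss, Loewe and ZIP synergy reference
    models plus the combination ratio, and an exact-binomial proportion test
    assesses whether inter-cluster combinations co-optimize efficacy and
    toxicity beyond chance. A synthetic-data module generates screens with
    planted drug clusters, cluster-biased target maps, cluster-correlated
    fingerprints and Hill-curve dose-response surfaces so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
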