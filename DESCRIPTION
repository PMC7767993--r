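Package: diconnect
Title: Network Connectivity Between a Focal Disease Gene Set and a Disease Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the association between a focal disease (e.g. type 1 or type 2
    diabetes) and a panel of other diseases from their gene sets on a
    protein-protein interaction (PPI) network. Implements ten method variants
    spanning four families: closest-distance (DIcd), gene-set overlap
    (DIoverlap), random-walk-with-restart plus running-sum enrichment (DINet),
    and weighted cross-edge counting (DIconnectivity), each on the whole
    network, on GO biological-process modularized subnetworks (MNs), on their
    RWR-expanded versions (eMNs), or with RWR-expanded gene sets (eDMN).
    Includes permutation z-score significance with BH/Bonferroni adjustment,
    functional-subnet specificity statistics (KF, AF, SP), key-connector
    identification by dynamic neighborhood search with hypergeometric
    enrichment, literature-Jaccard benchmark labelling with rank-based AUC,
    and a seeded synthetic interactome generator with planted modules for
    offline benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
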