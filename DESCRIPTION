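Package: gdforest
Title: Greedy Decision Forests for Explainable Network Module Detection
Version: 0.1.0
Author: gdforest developers
Maintainer: gdforest developers <gdforest@example.org>
Description: Detects small, high-performing functional modules in a
    domain-knowledge graph (for example a protein-protein interaction
    network) whose multi-modal node features predict a binary outcome.
    Decision trees are restricted to features of nodes visited by random
    walks on the graph; a greedy accept/shrink/resample loop evolves a
    population of such trees towards minimal subnetworks without losing
    out-of-bag performance. Dedicated scores rank modules, edges and
    per-modality features, and TreeSHAP-style attributions explain both
    the forest and single module trees. A synthetic benchmark plants
    Boolean-logic modules on scale-free graphs for self-contained testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
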