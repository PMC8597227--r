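Package: eoesgc
Title: miRNA-Disease Association Prediction via Coupled-Graph Embedding
    and Simplified Graph Convolution
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a known
    association matrix and a disease ontology. Builds disease similarity from
    two ontology-based semantic models and a Gaussian interaction-profile
    kernel, and miRNA similarity from functional similarity plus the same
    kernel; assembles a coupled heterogeneous graph; learns node embeddings
    with a link-based embedding-of-embedding (EOE) model whose harmony matrix
    aligns the two node types; propagates features over the bipartite
    association graph with a simplified graph convolution (SGC) operator; and
    scores pairs with a small multilayer perceptron. Ships a cross-validation
    and ranking harness with negative sampling, AUC/AUPR/F1 metrics, a
    dimension-sweep utility, synthetic fixture generators (random multi-rooted
    ontology DAGs, planted-block association matrices), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
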