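Package: kspnet
Title: Network and Sequence Based Prediction of Catalyzing Kinases for Phosphosites
Version: 0.1.0
Authors@R: person("KSP", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the catalyzing kinase of a protein phosphorylation site by
    combining a weighted path-product affinity score computed on an integrated
    kinase-substrate / protein-protein interaction network with two sequence
    scorers: per-kinase position weight matrices over 15-mer site-flanking
    peptides and a BLOSUM62 k-nearest-neighbour classifier. Includes score
    normalization and additive combination, a full ranking and evaluation
    harness (k-fold cross-validated top-k accuracy, per-kinase splits with
    matched negatives, confusion-matrix metrics, ROC and precision-recall
    curves), and a synthetic data generator with planted kinase-substrate
    links and sequence motifs for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
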