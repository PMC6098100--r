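Package: NetNetML
Title: Net-Net AutoML Screening of Neural Network Topologies for
    Ecological Link Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Net-Net AutoML methodology for biological
    ecosystem networks (BENs): Markov-chain walk distributions and Shannon
    entropy centralities (Sh_k, k = 0..5) are computed for the nodes of
    ecological interaction webs and, with the same machinery, for the
    neuron graphs of candidate artificial neural network (ANN) topologies.
    Species-pair feature tables (bsi) and meta-training tables (mt) pair
    node entropies with whole-topology descriptors, and a linear
    discriminant meta-classifier - plus a menu of nonlinear alternatives -
    predicts, before any training, whether a given ANN topology will
    correctly classify a given species-pair link. Includes a Pajek .net
    reader/writer, a synthetic bipartite food-web generator, confusion
    matrix and AUROC reporting, and a command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    nnet,
    rpart,
    randomForest,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
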