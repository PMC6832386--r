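Package: rwshin
Title: Signed Heterogeneous Network Embedding for Drug Side-Effect Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns low-dimensional drug embeddings from a signed
    heterogeneous drug information network built from chemical fingerprints,
    side-effect profiles, drug-target associations and signed drug-target
    action modes, and predicts drug side-effects per term with
    L2-regularized logistic regression under drug-wise cross-validation.
    Drug-drug subnetworks are built from Jaccard similarities of binary
    profiles and from a signed action-mode agreement score; node sequences
    are sampled with a structural-balance-aware biased random walk on the
    signed subnetwork and a BFS/DFS-biased walk on the unsigned
    subnetworks, and embeddings are trained with Skip-gram and negative
    sampling. Includes a synthetic-data generator with planted,
    sign-dependent group structure so the whole pipeline and the
    signed-versus-unsigned ablation are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'rwshin-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'network.R'
    'walks.R'
    'embedding.R'
    'prediction.R'
    'synthetic-data.R'
    'pipeline.R'
    'profiles-io.R'
    'utils.R'
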