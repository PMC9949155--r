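Package: phylotopo
Title: Learnable Topological Features for Phylogenetic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structural representation learning for phylogenetic tree
    topologies. Provides a linear-time two-pass algorithm that embeds
    interior nodes of a tree by Dirichlet-energy minimization with one-hot
    tip features, message-passing (graph neural network) feature learning
    on top of the embeddings, energy-based models over enumerated tree
    topology spaces trained by noise-contrastive estimation, Felsenstein
    pruning likelihood under the JC69 substitution model with analytic
    branch-length gradients, and variational Bayesian phylogenetic
    inference with subsplit-Bayesian-network topology distributions and
    split, primary-subsplit-pair, or learnable branch-length
    parameterizations trained with multi-sample (VIMCO) and
    reparameterization gradient estimators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
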