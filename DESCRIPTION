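Package: modalgate
Title: Uncertainty-Gated Ensembles of Uni-Modal and Multi-Modal Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-aware binary disease classification from paired tabular and
    image modalities. A cheap uni-modal classifier over per-region brain
    volumes is trained with an evidential (Dirichlet subjective-logic) head or
    with Monte-Carlo dropout; its per-instance predictive uncertainty gates
    whether the expensive second modality (paired lateral surface-projection
    images) is requested and a late-fusion multi-modal classifier is invoked.
    Includes the evidential sum-of-squares loss and subjective-logic opinion
    math, a compact neural-network training engine (multilayer perceptrons and
    residual convolutional branches), simple and embedding-distance gating
    policies, accuracy/cost frontier sweeps, out-of-distribution uncertainty
    evaluation under region masking and image rotation, random-forest
    explanation of referral decisions, and a seeded synthetic cohort generator
    emulating the paired-modality data shape.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
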