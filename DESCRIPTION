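Package: latentcca
Title: Latent Brain-Behaviour Dimensions via Regularized CCA with
    Multiple-Holdout Validation, Restricted Permutation Inference and
    Twin-Based Variance Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers, validates and genetically characterises latent
    dimensions linking a behavioural data view to a multi-feature
    brain-structure view. Implements regularized canonical correlation
    analysis (weights, scores, loadings, deflation), a multiple-holdout
    machine-learning framework with family-aware nested data splits and
    leakage-free preprocessing, family-restricted permutation tests with an
    omnibus decision over outer splits, spherical spin tests for comparing
    parcellated surface maps, and AE twin-model variance decomposition
    (heritability, genetic and environmental correlation) of the latent
    scores. Ships a synthetic-cohort generator with planted latent
    structure, twin families and spatially smooth parcel loadings so the
    whole pipeline is testable with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort-sim.R'
    'framework.R'
    'gridsearch.R'
    'io.R'
    'latentcca-package.R'
    'permutation.R'
    'preprocess.R'
    'quantgen.R'
    'rcca.R'
    'replicability.R'
    'splits.R'
    'utils.R'
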