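Package: perd
Title: Predict Enhancers Responsive to Drug from Perturbed Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts enhancer chromatin accessibility (DNase I
    hypersensitivity derived "openness") from the expression of each
    enhancer's binding transcription factors and associated target genes,
    using one regularized regression model per enhancer (elastic net,
    random forest, or support vector backends). Fitted models are applied
    to control and drug-treated expression profiles to call
    drug-responsive enhancers by differential predicted openness
    (empirical-Bayes moderated t-test or Wilcoxon rank-sum), and the
    called enhancers are annotated with motif sites, drug-perturbed
    target genes, and regulatory variants that fall inside them. Includes
    builders for the enhancer-gene and TF-enhancer prior networks,
    evaluation statistics (cross-cell and cross-enhancer correlation,
    normalized squared prediction error), predictability filtering on
    DH-signal properties, and a synthetic-data generator with full ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    randomForest,
    e1071,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
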