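Package: gitnet
Title: Genomic Impact Transformer: Attention-Based Modeling of Somatic
    Alterations and Their Transcriptomic Impact
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the genomic impact transformer (GIT), an
    encoder-decoder neural network that maps the set of somatic genomic
    alterations (SGAs) observed in a tumor to its differentially
    expressed genes (DEGs).  Gene embeddings are pre-trained from
    within-tumor SGA co-occurrence with a skip-gram negative-sampling
    model (Gene2Vec) and refined by a multi-head self-attention encoder
    whose attention weights rank candidate driver genes.  The package
    ships a synthetic tumor-cohort simulator with planted driver
    pathways, baseline models (lasso, multilayer perceptrons), an
    ablation harness, embedding-quality metrics (nearest-neighbour
    accuracy, cluster annotation enrichment), and downstream phenotype
    pipelines for survival (elastic-net Cox) and drug-response
    (cross-validated lasso) prediction from tumor embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    pROC,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
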