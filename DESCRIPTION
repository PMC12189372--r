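Package: rbpstack
Title: Stacked Ensemble and Convolutional Classification of RNA-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of plant RNA-binding proteins (RBPs)
    from amino-acid composition alone. Protein sequences are encoded as
    k-peptide composition (KPC) frequency vectors (amino-acid and dipeptide
    composition by default), enriched with out-of-fold prediction columns
    from a stack of base classifiers (RBF-kernel SVM, ridge-regularised
    logistic regression, linear discriminant analysis, and a leaf-wise
    histogram gradient-boosted tree model), pruned by Pearson-correlation
    analysis with AUC-guided tie-breaking, and classified by an
    embedding-free multi-kernel 1D convolutional network with scaled
    dot-product self-attention over the pooled branch representations.
    Includes confusion-matrix metrics (accuracy, MCC, sensitivity,
    specificity, F1, precision, AUC), stratified k-fold cross-validation with
    leakage-safe per-fold refitting, ablation tables with paired one-tailed
    t-tests, and a seeded synthetic benchmark generator that plants k-peptide
    motifs into a background composition so the whole pipeline is exercisable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    glmnet,
    jsonlite,
    MASS,
    Rcpp,
    ranger,
    rpart,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
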