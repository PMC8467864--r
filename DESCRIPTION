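Package: seqstab
Title: Sequence-Based Classification of Mechanically Stable Protein
    Substructures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein residues into mechanically stable (S) and
    unstable (U) substructure classes from sequence information alone.
    Builds context-dependent physico-chemical features by a centered
    Gaussian moving average over 28 literature amino-acid scales, provides
    unsupervised diagnostics (PCA with informative 2D projection scoring,
    Fisher linear discriminant analysis), supervised classification
    (logistic regression, random forest, support vector machine) with
    leakage-aware train/test splitting, greedy forward feature selection,
    grid optimization and stratified cross-validation with border-aware
    misclassification mapping, a shuffled-scale negative control, and
    multiple-sequence-alignment conservation statistics (Wu-Kabat
    variability, conserved positions, pairwise identity). Includes a
    seeded synthetic-data generator of labeled sequences and alignments so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    randomForest,
    e1071,
    jsonlite,
    Biostrings
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
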