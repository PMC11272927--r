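Package: tastekit
Title: Four-Class Molecular Taste Prediction with Evolutionary Model Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the taste class (bitter, sweet, umami or other) of small
    molecules and peptides from 2D molecular structure. Implements the full
    pipeline: ingestion and standardization of SMILES/InChI/FASTA input, a
    1613-column 2D molecular descriptor catalogue (autocorrelation, spectral,
    E-state, connectivity and count families), missing-value filtering and
    kNN imputation, non-parametric feature screening (Kruskal-Wallis with
    Benjamini-Hochberg control), a nine-objective Pareto-based evolutionary
    optimizer that jointly selects features, classifier family (random forest
    or SVM) and hyperparameters under stratified cross-validation with
    boosting-style minority oversampling, tree Shapley explanations, and a
    Tanimoto-similarity applicability domain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    ranger,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    yaml
SystemRequirements: OpenBabel (obabel on PATH)
Config/testthat/edition: 3
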