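# tastekit

Four-class molecular taste prediction — **bitter / sweet / umami / other** —
from two-dimensional structure alone, for food chemists, flavour researchers
and cheminformaticians who need a tested, fully scriptable pipeline from raw
molecular notations to explained, applicability-scored predictions.

## What it implements

Given compounds as SMILES, InChI, SMARTS or peptide sequences, tastekit:

1. **curates** them — canonical standardized parent structures (parse check,
   neutralization, salt stripping), duplicate and cross-label-conflict
   removal, seeded per-class train/test partitioning;
2. **describes** them — a catalogue of 1613 named 2D descriptors
   (Moreau–Broto/Moran/Geary autocorrelation over 12 atomic weightings,
   matrix-spectral suites on adjacency/Laplacian/distance/Barysz/Burden
   matrices, E-state statistics, connectivity and shape indices, information
   content, path/walk counts, VSA-style surface partitions, and count/
   physicochemical descriptors), with >30%-missing filtering, kNN imputation
   (k = 20) and [0, 1] min–max normalization;
3. **screens** features — per-feature Kruskal–Wallis across the classes with
   Benjamini–Hochberg control (selection at q < 0.05), one-vs-rest
   Mann–Whitney rankings and PCA projections;
4. **builds the model** — a nine-objective Pareto-based evolutionary search
   over feature subsets, classifier family (random forest vs RBF-SVM) and
   hyperparameters. Objectives: ACC, F1, F2, precision, recall, AUC (from
   stratified 10-fold cross-validation with boosting-style minority
   oversampling applied inside each training fold), feature-count and
   model-complexity minimization, and a Manhattan probability-distance score;
   scalar fitness is the weighted sum with weights 1/10/10/1/1/10/1/1/1
   (maximum 36). Defaults: population 100, 200 generations, two-point
   crossover 0.9, mutation 0.01, ten independent runs;
5. **explains** it — exact path-dependent tree Shapley values per class
   (local accuracy: base value + attribution sum = predicted probability),
   global importance ranking, feature correlation;
6. **scores applicability** — 1024-bit radius-2 circular fingerprints, mean
   Tanimoto similarity to the 5 nearest training compounds, and per-decile
   performance stratification.

The methods vignette (`vignettes/tastekit-methods.Rmd`) documents the model,
parameters and design decisions in detail.

## Worked example

```r
library(tastekit)

recs <- standardize_molecules(fixture_molecules())  # 32 curated inputs
recs <- deduplicate_molecules(recs)                 # 29 unique structures
tab  <- compute_descriptors(recs)
#> DescriptorTable: 29 compounds x 1613 features [state: raw, 22.8% missing]
tab  <- knn_impute(drop_sparse_features(tab), k = 5)
#> DescriptorTable: 29 compounds x 1113 features [state: imputed, 0.0% missing]

spec  <- classifier_spec("random_forest", n_trees = 95, seed = 1)
model <- build_predictor(tab, recs$label, tab$features[1:40], spec,
                         train_smiles = recs$canonical_smiles)

new    <- standardize_molecules(molecule_records(c("OCC(O)C(O)CO", "FNKEE")))
newtab <- compute_descriptors(new)
predict_taste(model, newtab)
#>      id predicted bitter  sweet other umami
#> 1 cmpd1     sweet  0.053 0.8735 0.059 0.014
#> 2 cmpd2     umami  0.052 0.0039 0.114 0.830
```

The first query (erythritol, written as SMILES) is predicted sweet with
probability 0.87; the second (the peptide FNKEE, auto-detected as a FASTA
sequence and condensed to its L-peptide SMILES) is predicted umami with
probability 0.83. Per-class probabilities always sum to 1 over the fixed
class order (bitter, sweet, other, umami). Adding
`avg_topk_similarity(morgan_fingerprint(new$canonical_smiles), model$train_fps)`
gives the applicability scores (here 0.60 and 0.59: both queries sit inside
the toy model's chemical space).

For the full search on a dataset, see `?evolve` / `?evolve_runs`, or the
command-line front end `inst/cli/tastekit` (subcommands `simulate`, `screen`,
`evolve`, `train`, `predict`, `explain`, `adscore`).

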