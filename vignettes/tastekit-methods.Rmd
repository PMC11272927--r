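---
title: "Predicting taste classes from 2D molecular structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting taste classes from 2D molecular structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tastekit predicts which of four taste classes — bitter, sweet, umami, or
other — a small molecule or peptide elicits, using only its two-dimensional
structure. This vignette explains the statistical model and procedure behind
each stage, the tunable parameters and their defaults, and the design
decisions taken where the methodology left genuine choices open.

## The problem and the pipeline

Taste perception is initiated by compound–receptor binding, and compounds
that taste alike tend to share physicochemical properties: charge
distribution, electronegativity and polarizability patterns are the strongest
known correlates. The pipeline turns a heterogeneous compound list into a
single-label four-class classifier in six stages:

1. **Curation** (`standardize_molecules`, `deduplicate_molecules`): every
   input — SMILES, InChI, SMARTS or a peptide sequence — is resolved to a
   canonical standardized parent structure: parse check, charge
   neutralization, and largest-fragment extraction (salts and solvates are
   stripped). The canonical SMILES of the parent is the identity key; a
   structure recorded with two conflicting taste labels is removed entirely,
   because a single-label classifier cannot learn from it and either label
   would be arbitrary.
2. **Descriptors** (`compute_descriptors`): a catalogue of 1613 named 2D
   descriptors per compound (next section).
3. **Pre-processing** (`drop_sparse_features`, `knn_impute`,
   `fit_normalization`): features missing in strictly more than 30% of
   compounds are discarded; remaining gaps are filled by k-nearest-neighbour
   imputation with k = 20 (Euclidean distance on mutually observed,
   mean-scaled features, k capped at the number of eligible rows); every
   feature is then min–max normalized to [0, 1]. Normalization parameters are
   fitted on training data only and frozen into the model bundle; at
   prediction time out-of-range values are clipped into [0, 1].
4. **Screening** (`screen_features`): a per-feature Kruskal–Wallis rank test
   across the four classes with Benjamini–Hochberg control and selection at
   q < 0.05. The non-parametric test is used because descriptor distributions
   are generally non-normal (the Shapiro–Wilk diagnostic is computed and
   reported, but never gates selection — it only justifies the rank test).
   One-vs-rest Mann–Whitney comparisons and a 3-component PCA projection are
   produced as descriptive companions.
5. **Model construction** (`evolve`): a nine-objective Pareto-based
   evolutionary search over feature subsets, classifier family (random forest
   vs RBF-SVM) and hyperparameters, evaluated by stratified 10-fold
   cross-validation with boosting-style minority oversampling inside each
   fold (below).
6. **Explanation and applicability** (`shapley_values`, `rank_features`,
   `avg_topk_similarity`): exact path-dependent tree Shapley attributions per
   class, global importance as the mean over classes of mean |attribution|,
   and an applicability-domain score — the mean Tanimoto similarity of a
   query's 1024-bit circular fingerprint to its 5 nearest training
   compounds — with performance reported per similarity decile.

## The descriptor catalogue

The catalogue contains exactly 1613 two-dimensional descriptors, the size of
the standard 2D descriptor set this field works with. Structure perception
(parsing, aromaticity, hybridization, Gasteiger charges) is delegated to
OpenBabel; all descriptor mathematics is implemented in the package on the
heavy-atom graph. The families:

| family | count | content |
|---|---|---|
| autocorrelation | 768 | Moreau–Broto (ATS, lag 0–10), averaged (AATS), centered (ATSC/AATSC), Moran (MATS, lag 1–10), Geary (GATS) over 12 atomic weightings |
| matrix-spectral | 325 | 13 eigenvalue statistics (SpAbs, SpMax, SpDiam, SpAD, SpMAD, LogEE, SM1, VE1–3, VR1–3) of the adjacency, Laplacian, normalized Laplacian, distance and Harary matrices, plus Barysz weighted-distance matrices (8 weightings) and Burden matrices (12 weightings) |
| E-state | 240 | count/sum/min/max of Kier–Hall electrotopological states over 35 specific atom types and 25 aggregate atom classes |
| connectivity | 48 | Randić/Kier–Hall path chi (orders 0–7, simple and valence, sums and means), ring chi (3–7), Kier shape indices 1–3 (plain and alpha-modified) |
| information content | 40 | Shannon information of Weisfeiler–Lehman-refined atom equivalence classes, orders 0–7 (IC, TIC, SIC, CIC, BIC) |
| path and walk counts | 43 | simple path counts (orders 1–10), pi-bond-order-weighted path counts, molecular walk counts, self-returning walks |
| VSA-style | 34 | approximate Labute van der Waals surface areas binned by Gasteiger charge (PEOE_VSA) and E-state (EState_VSA, VSA_EState) |
| counts and composition | 115 | atom/bond/ring/carbon-type counts, constitutional property sums and means, molecular distance-edge, topological indices (Wiener, Zagreb, Balaban J, Bertz complexity, eccentric connectivity, ABC), physicochemical properties (MW, logP, MR, TPSA, H-bond counts, McGowan volume, polarizabilities) |

The 12 atomic weightings are Gasteiger charge, valence delta, sigma degree,
intrinsic state, atomic number, mass, van der Waals volume, Sanderson /
Pauling / Allred–Rochow electronegativities, polarizability and first
ionization potential. For the charge weighting, each heavy atom carries its
own Gasteiger partial charge (attached-hydrogen charges are not folded in).
Descriptors that are undefined for a molecule — a lag with no atom pairs, a
single-atom graph, an element outside the parameter tables — are recorded as
missing, never as zero; the >30% missing filter then removes systematically
incomputable columns on real datasets. Column values are this package's own
implementations of the cited descriptor definitions; they are not claimed to
be numerically interchangeable with any other engine's columns of the same
name.

Fingerprints for the applicability domain are a separate representation:
hashed circular substructure fingerprints of radius 2 folded by OR to 1024
bits (length, determinism and structural-identity behaviour are contract;
specific bit positions are engine-dependent).

## Class balancing and cross-validation

The curated taste corpus is umami-poor (227 umami versus 360 per other class
in the training quotas), so every model fit balances its training data by
boosting-style oversampling: sample weights start uniform, the
still-deficient minority class has its weights uprated each round, and
members are drawn with probability proportional to weight and duplicated
(flagged as synthetic) until all classes match the majority count. Copies are
weighted duplicates, not interpolations. Balancing the published quotas adds
exactly 133 umami copies. Crucially, oversampling happens *inside* each
cross-validation fold, on the training portion only — synthetic copies can
never reach a validation fold, which the test suite asserts structurally.

Evaluation uses stratified 10-fold cross-validation; fold assignment
continues a round-robin across classes so that per-class counts differ by at
most one *and* fold totals stay balanced. The metric suite is accuracy;
one-vs-rest precision, recall, F1 and F2 averaged with class-support weights
(weighted recall then equals accuracy, which makes the two directly
comparable across reports); and support-weighted one-vs-rest ROC-AUC computed
by the rank (Mann–Whitney) estimator — the fast inner-loop route, verified
against an independent ROC implementation in the tests.

## The evolutionary optimizer

A candidate model is a genome: a feature bit-mask, one family gene (random
forest or SVM) and two real-coded hyperparameter genes in [0, 1] mapped to
10–200 trees, or to C and gamma on a log grid from 1e-3 to 1e3 (the paper
names the parameters but not ranges; the log grid is the conventional SVM
search space). Each evaluated candidate receives nine objectives in [0, 1]:

* six CV performance metrics (ACC, F1, F2, precision, recall, AUC);
* feature-count minimization, as 1 − (selected / candidates);
* model-complexity minimization (trees or support vectors), as 1 − count/max;
* a Manhattan-distance score: 1 − (mean L1 distance between the CV-predicted
  class-probability vector and the one-hot true label)/2. The source
  methodology names a "Manhattan distance" objective without defining it;
  this is the only distance-flavoured quantity computable per candidate from
  the CV predictions, and it is isolated in a single replaceable scoring
  function (`manhattan_score`) should a better reading emerge.

Scalar fitness is the weighted sum with weights 1 (features), 10 (ACC), 10
(F1), 1 (F2), 1 (precision), 10 (recall), 1 (AUC), 1 (complexity), 1
(Manhattan) — maximum 36. The generational loop is: size-2 tournament
selection on scalar fitness with Pareto-rank tie-break (no selection scheme
is prescribed by the source; tournament is the standard default), two-point
crossover on the concatenated genome at probability 0.9, per-gene mutation at
0.01 (bit-flip for mask and family, clipped Gaussian for the real genes),
arithmetic crossover at probability 0, and elitism that carries the current
Pareto front (trimmed to half the population by scalar fitness if oversized).
Defaults are a population of 100 for 200 generations, repeated over 10
independent runs whose metric means and SDs `evolve_runs` aggregates. The 5%
mean-versus-best convergence flag in the history is diagnostic only; the
stopping rule is the generation budget. Evaluations are memoized by genome,
and identical seeds reproduce identical fronts bit for bit. An empty feature
mask is repaired to a single random bit before evaluation. Final-model
selection defaults to the knee point (maximum scalar fitness, ties broken
toward fewer features), with `fewest_features`, `max_accuracy` or an explicit
index available for the manual choice the front invites.

## Explanation

For tree models the package computes exact path-dependent tree Shapley
values: per tree, the recursion tracks the proportion of training cover
flowing down each branch and yields attributions whose sum plus the base
value reproduces the predicted class probability to numerical precision
(asserted at 1e-6 in the suite; observed at machine precision). Covers are
recomputed by routing the stored training matrix through each tree. The
forest attribution is the per-tree average. Non-tree models fall back to a
seeded permutation-sampling approximation, flagged as such in the result.
Global importance is the mean over classes of the mean absolute attribution,
ranked descending with alphabetical tie-break; the attribution reference set
is the training table. Feature correlation for the companion heatmap is
Pearson, the conventional choice for descriptor correlation panels.

## Applicability domain

A query is scored by the mean Tanimoto similarity between its fingerprint
and its 5 most similar training fingerprints (all of them if fewer than 5;
when scoring training compounds against their own set the identical
fingerprint can be excluded). Test compounds are then divided into 10
equal-frequency similarity bins — the source text says "10 quartiles", which
can only mean deciles — and the metric suite is evaluated per bin; duplicate
quantile edges are merged and flagged. A model with a healthy applicability
domain shows per-decile accuracy statistically indistinguishable from the
global accuracy.

## The synthetic data generator

`generate_dataset` emulates the statistical structure the pipeline assumes,
so every stage is testable without any external download: features are
log-normal (sdlog drawn once per feature from 0.4–0.8), which reliably fails
Shapiro–Wilk at moderate n, as real descriptor distributions do; a planted
informative subset carries class-dependent additive location shifts, with the
four classes at equally spaced offsets spanning `shift` population SDs in a
per-feature random class order; features share latent factors in blocks
(log-scale loading 0.5) to mimic correlated descriptor families; cells go
missing completely at random at `missing_rate`, and a designated few features
are pushed above the 30% threshold to exercise the sparse filter; the default
class sizes 360/360/227/360 mirror the curated training quotas, including
the umami shortfall. The generator returns the planted truth mask, making
informative-feature recovery by the full screen-then-evolve pipeline the
primary end-to-end check.

What the generator does *not* emulate: real descriptor inter-dependence
(deterministic functional relationships between descriptor families),
heavy-tailed label noise, multi-modal within-class structure, and any actual
chemistry. Passing the synthetic suites therefore demonstrates that the
machinery is correct and calibrated — not that any particular real-world
accuracy will be attained, which depends on the curated corpus.

## Numerical choices and degenerate inputs

* Thresholds follow strict inequalities where stated (">30%" missing).
* Constant features normalize to 0; zero-variance features are flagged and
  excluded from selection; constant samples make Shapiro–Wilk undefined and
  are treated as non-normal.
* Kruskal–Wallis on all-equal observations returns H = 0 (identical ranks)
  rather than the 0/0 the tie-correction formula produces.
* Ties in rank tests use average ranks with tie correction throughout.
* AUC for a class absent from the truth set is undefined, flagged, and
  dropped from the support-weighted average.
* Peptides are assembled with L-stereocentres (the biological default; the
  source is silent) and free termini.
* PubChem name resolution is a disabled stub behind an optional resolver
  argument — the core has no network dependency.
* Problem sizes in the test and acceptance suites are scaled-down study
  conditions chosen once: recovery runs use 60 compounds per class, 50
  candidate features with 5 informative at 2-SD shifts, a population of 30
  for 40 generations with 5-fold CV inside the evaluator, and five seeded
  repetitions; the null-calibration study uses 100 repetitions of a 120 x 50
  null table. These sizes give the checks high power while keeping a full
  suite run on a single CPU comfortable.

## Known limitations

* Descriptor values are engine-specific implementations of the cited
  definitions; models trained on another engine's tables are not
  interchangeable with tastekit tables column-for-column.
* The Gasteiger-charge weighting inherits OpenBabel's charge model; elements
  outside its parameterization yield missing charge-weighted descriptors.
* Exact tree Shapley cost grows with tree depth squared per leaf; explaining
  very large forests on many samples is slow (the CLI caps explained samples
  at 50 by default).
* The SVM branch calibrates probabilities by pairwise coupling, which is
  seeded but adds its own variance; the optimizer in practice favours the
  random-forest family, consistent with the source findings.
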