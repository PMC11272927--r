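# Seeded generators: fixture molecules spanning the four taste classes (with
# curation edge cases) and synthetic descriptor datasets emulating the
# statistical structure the pipeline assumes.

#' Fixture molecules for the curation pipeline
#'
#' About thirty hard-coded structures covering the four taste classes plus
#' curation edge cases: a salt, a duplicate pair written in two SMILES
#' spellings, an invalid SMILES, and three umami peptides supplied as FASTA
#' sequences (FLNQDEEAR, FNKEE, EEFLK).
#'
#' @return molecule records ready for [standardize_molecules()]
#' @export
fixture_molecules <- function() {
  fix <- list(
    # bitter
    c("caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "bitter"),
    c("theobromine", "Cn1cnc2c1c(=O)[nH]c(=O)n2C", "bitter"),
    c("nicotine", "CN1CCC[C@H]1c1cccnc1", "bitter"),
    c("quinoline", "c1ccc2ncccc2c1", "bitter"),
    c("naringenin", "Oc1ccc(cc1)C1CC(=O)c2c(O)cc(O)cc2O1", "bitter"),
    c("phenylthiourea", "NC(=S)Nc1ccccc1", "bitter"),
    c("salicin_like", "OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O", "bitter"),
    # sweet
    c("sucrose", "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O", "sweet"),
    c("glucose", "OCC1OC(O)C(O)C(O)C1O", "sweet"),
    c("fructose", "OCC1(O)OCC(O)C(O)C1O", "sweet"),
    c("xylitol", "OCC(O)C(O)C(O)CO", "sweet"),
    c("sorbitol", "OCC(O)C(O)C(O)C(O)CO", "sweet"),
    c("saccharin", "O=C1NS(=O)(=O)c2ccccc12", "sweet"),
    c("glycerol", "OCC(O)CO", "sweet"),
    c("erythritol", "OCC(O)C(O)CO", "sweet"),
    # umami (monosodium glutamate enters as its sodium salt: curation strips it)
    c("glutamate_na", "N[C@@H](CCC(=O)[O-])C(=O)O.[Na+]", "umami"),
    c("aspartate", "N[C@@H](CC(=O)O)C(=O)O", "umami"),
    c("inosinate_core", "O=c1[nH]cnc2c1ncn2C1OC(CO)C(O)C1O", "umami"),
    c("succinate", "OC(=O)CCC(=O)O", "umami"),
    # other
    c("ethanol", "CCO", "other"),
    c("acetic_acid", "CC(=O)O", "other"),
    c("menthol", "CC(C)C1CCC(C)CC1O", "other"),
    c("capsaicin_core", "COc1cc(CNC(=O)CCCC\\C=C\\C(C)C)ccc1O", "other"),
    c("citric_acid", "OC(=O)CC(O)(CC(=O)O)C(=O)O", "other"),
    c("benzaldehyde", "O=Cc1ccccc1", "other"),
    c("eugenol", "COc1cc(CC=C)ccc1O", "other"),
    # curation edge cases
    c("dup_ethanol_spelling", "OCC", "other"),
    c("invalid_ring", "C1CC", "other"),
    c("acetate_salt", "CC(=O)[O-].[Na+]", "other")
  )
  rec <- molecule_records(
    input = vapply(fix, `[[`, "", 2),
    id = vapply(fix, `[[`, "", 1),
    label = vapply(fix, `[[`, "", 3),
    format = rep("smiles", length(fix))
  )
  pep <- molecule_records(
    input = c("FLNQDEEAR", "FNKEE", "EEFLK"),
    id = c("FR-9", "FE-5", "EK-5"),
    label = rep("umami", 3),
    format = rep("fasta", 3)
  )
  rbind(rec, pep)
}

#' Generate a synthetic four-class descriptor dataset
#'
#' Emulates the statistical structure of a curated taste descriptor table:
#' right-skewed (log-normal) feature distributions that fail normality tests,
#' class-dependent location shifts planted in a known informative subset,
#' correlated feature blocks driven by shared latent factors, missing cells,
#' a few features pushed above the 30% missing threshold, and umami-style
#' class imbalance.
#'
#' @param n_per_class named counts per class; the default mirrors the
#'   training quotas of the curated study data (360 bitter, 360 sweet,
#'   227 umami, 360 other)
#' @param n_features total features
#' @param n_informative features carrying a class signal (the planted truth)
#' @param shift total class separation of an informative feature, in units of
#'   the feature's population SD (classes sit at equally spaced offsets
#'   spanning `shift` SDs, in a per-feature random class order)
#' @param missing_rate fraction of cells set missing completely at random
#' @param corr_block_size features per correlated (shared latent factor) block
#' @param n_sparse_features features forced above the 30% missing threshold
#' @param seed RNG seed; identical seeds give bit-identical datasets
#' @return list: `table` (raw DescriptorTable), `labels`, `truth_mask`
#'   (logical over features), `config`
#' @export
generate_dataset <- function(n_per_class = c(bitter = 360, sweet = 360, umami = 227, other = 360),
                             n_features = 50L, n_informative = 5L,
                             shift = 1.5, missing_rate = 0.02,
                             corr_block_size = 5L, n_sparse_features = 2L,
                             seed = 1L) {
  tk_assert(n_informative <= n_features, "n_informative exceeds n_features")
  tk_assert(
    missing_rate >= 0 && missing_rate < 1,
    "missing_rate must lie in [0,1)"
  )
  set.seed(seed)
  classes <- names(n_per_class)
  y <- rep(classes, n_per_class)
  n <- length(y)
  sigma <- runif(n_features, 0.4, 0.8)
  rho <- 0.5 # latent-factor loading within a correlated block (log scale)
  block <- ((seq_len(n_features) - 1) %/% corr_block_size) + 1
  Z <- matrix(rnorm(n * n_features), n, n_features)
  FACT <- matrix(rnorm(n * max(block)), n, max(block))
  logX <- sweep(
    sqrt(1 - rho^2) * Z + sqrt(rho^2) * FACT[, block, drop = FALSE],
    2, sigma, "*"
  )
  X <- exp(logX)
  # plant class shifts on the informative subset (additive on the raw scale,
  # preserving the skewed shape)
  truth <- seq_len(n_features) <= n_informative
  popsd <- sqrt((exp(sigma^2) - 1) * exp(sigma^2))
  for (j in which(truth)) {
    offs <- (seq_along(classes) - 1) / (length(classes) - 1) - 0.5
    offs <- sample(offs) * shift * popsd[j]
    X[, j] <- X[, j] + offs[match(y, classes)]
  }
  # missingness: MCAR everywhere, plus designated sparse features
  if (missing_rate > 0) {
    X[matrix(runif(n * n_features) < missing_rate, n, n_features)] <- NA
  }
  sparse_idx <- integer(0)
  if (n_sparse_features > 0) {
    sparse_idx <- seq(n_features - n_sparse_features + 1, n_features)
    for (j in sparse_idx) {
      X[sample.int(n, ceiling(0.35 * n)), j] <- NA
    }
  }
  colnames(X) <- sprintf("feat%03d", seq_len(n_features))
  rownames(X) <- sprintf("s%04d", seq_len(n))
  list(
    table = descriptor_table(X, state = "raw",
      log = sprintf("synthetic dataset, seed %d", seed)),
    labels = y,
    truth_mask = truth,
    config = list(
      n_per_class = n_per_class, n_features = n_features,
      n_informative = n_informative, shift = shift,
      missing_rate = missing_rate, corr_block_size = corr_block_size,
      n_sparse_features = n_sparse_features, seed = seed
    )
  )
}
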