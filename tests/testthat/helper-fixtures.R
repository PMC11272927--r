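# Shared in-code fixtures.

# A small labelled, well-separated synthetic matrix for model tests.
make_separable <- function(n_per_class = 50, n_features = 30, n_informative = 10,
                           shift = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("bitter", "sweet", "other", "umami"), each = n_per_class)
  X <- matrix(rnorm(length(y) * n_features), ncol = n_features)
  colnames(X) <- paste0("f", seq_len(n_features))
  for (j in seq_len(n_informative)) {
    X[, j] <- X[, j] + shift * as.integer(factor(y))
  }
  rownames(X) <- paste0("s", seq_along(y))
  list(X = X, y = y)
}

# obabel canonical SMILES for oracle comparisons in chemistry tests.
obabel_canonical <- function(smiles) {
  out <- system2("obabel", c("-ismi", "-ocan"),
    input = smiles, stdout = TRUE, stderr = FALSE)
  out <- trimws(out[nzchar(trimws(out))])
  strsplit(out[1], "[ \t]+")[[1]][1]
}

# Count SMARTS matches with OpenBabel (independent substructure oracle).
smarts_count <- function(smiles, pattern) {
  mols <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  as.numeric(ChemmineOB::smartsSearch_OB(mols, pattern))
}
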