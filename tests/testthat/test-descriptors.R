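# Descriptor catalogue and computation.

test_that("the catalogue holds 1613 uniquely named 2D descriptors", {
  cat_names <- descriptor_catalogue()
  expect_length(cat_names, 1613)
  expect_false(anyDuplicated(cat_names) > 0)
  fams <- descriptor_catalogue(by_family = TRUE)
  expect_equal(sum(lengths(fams)), 1613)
})

test_that("descriptor rows match hand-derived values on small molecules", {
  tab <- compute_descriptors(c("C", "CC", "CCC", "c1ccccc1"))
  v <- tab$values
  expect_equal(ncol(v), 1613)
  # methane: 1x1 adjacency matrix, spectral diameter 0
  expect_equal(v[1, "SpDiam_A"], 0)
  # ethane, lag-0 Moreau-Broto with atomic-number weights: 2 * 6^2
  expect_equal(v[2, "ATS0Z"], 72)
  expect_equal(v[2, "AATS0Z"], 36)
  # ethane, lag-1: one pair at distance 1 -> 6*6
  expect_equal(v[2, "ATS1Z"], 36)
  # propane Wiener index: d(1,2)+d(2,3)+d(1,3) = 4
  expect_equal(v[3, "WPath"], 4)
  # propane simple path chi order 1: two bonds, each (1*2)^(-1/2)
  expect_equal(v[3, "Xp1"], 2 / sqrt(2), tolerance = 1e-12)
  # benzene: 6 aromatic atoms, one ring, Zagreb1 = 6*2^2
  expect_equal(v[4, "nAromAtom"], 6)
  expect_equal(v[4, "nRing"], 1)
  expect_equal(v[4, "Zagreb1"], 24)
  # benzene adjacency spectrum is {2,1,1,-1,-1,-2}: SpDiam 4, SpAbs 8
  expect_equal(v[4, "SpDiam_A"], 4, tolerance = 1e-9)
  expect_equal(v[4, "SpAbs_A"], 8, tolerance = 1e-9)
})

test_that("lag-0 autocorrelation with unit weights equals the heavy-atom count", {
  # direct-summation oracle: ATS0 with w = 1 is sum of squared unit weights
  tab <- compute_descriptors(c("CC", "CCO", "c1ccccc1"))
  # ATS0 scales as sum(w_i^2); with the constant atomic-number weight of
  # carbon-only molecules, ATS0Z / Z_C^2 recovers the atom count
  expect_equal(tab$values[1, "ATS0Z"] / 36, 2)
  expect_equal(tab$values[3, "ATS0Z"] / 36, 6)
  # heteroatom oracle: CCO -> 6^2 + 6^2 + 8^2
  expect_equal(tab$values[2, "ATS0Z"], 36 + 36 + 64)
})

test_that("descriptor computation is deterministic and records failures as missing", {
  t1 <- compute_descriptors(c("CCO", "CC(=O)O"))
  t2 <- compute_descriptors(c("CCO", "CC(=O)O"))
  expect_identical(t1$values, t2$values)
  # methane has no bonded pairs: lag-1 autocorrelation must be missing, not 0
  tm <- compute_descriptors("C")
  expect_true(is.na(tm$values[1, "ATS1Z"]))
  expect_true(is.na(tm$values[1, "Xp1"]) || tm$values[1, "Xp1"] == 0)
})

test_that("sparse-feature dropping uses a strict 30% rule", {
  X <- matrix(rnorm(300), nrow = 100, ncol = 3,
    dimnames = list(NULL, c("drop31", "keep30", "full")))
  X[1:31, "drop31"] <- NA
  X[1:30, "keep30"] <- NA
  tab <- descriptor_table(X, state = "raw")
  out <- drop_sparse_features(tab)
  expect_setequal(out$features, c("keep30", "full"))
  expect_equal(attr(out, "dropped"), "drop31")
  expect_equal(out$state, "filtered")
  allna <- descriptor_table(matrix(NA_real_, 10, 2,
    dimnames = list(NULL, c("a", "b"))), state = "raw")
  expect_error(drop_sparse_features(allna), "all features")
})

test_that("kNN imputation reproduces the brute-force neighbour mean", {
  X <- matrix(c(1, 3, 2, 1, 3, NA), nrow = 3,
    dimnames = list(c("r1", "r2", "r3"), c("a", "b")))
  tab <- descriptor_table(X, state = "filtered")
  out <- knn_impute(tab, k = 2)
  # nearest two rows by the observed feature 'a' are r1 and r2: mean(1,3) = 2
  expect_equal(out$values["r3", "b"], 2)
  # observed cells are bit-identical
  expect_identical(out$values[1:2, ], X[1:2, ])
  # k larger than the row count falls back to all rows
  out2 <- knn_impute(tab, k = 50)
  expect_equal(out2$values["r3", "b"], 2)
  # a fully observed table passes through unchanged
  full <- descriptor_table(matrix(1:6, 2, dimnames = list(NULL, c("a", "b", "c"))) * 1.0,
    state = "filtered")
  expect_identical(knn_impute(full, 3)$values, full$values)
  # a row with nothing observed cannot be imputed
  Xbad <- matrix(c(1, NA, 2, NA), 2, dimnames = list(c("x", "y"), c("a", "b")))
  expect_error(knn_impute(descriptor_table(Xbad, state = "filtered")), "all features missing")
})

test_that("min-max normalization maps endpoints, constants and out-of-range values", {
  X <- matrix(c(2, 4, 6, 5, 5, 5), ncol = 2, dimnames = list(NULL, c("v", "const")))
  tab <- descriptor_table(X, state = "imputed")
  params <- fit_normalization(tab)
  out <- apply_normalization(tab, params)
  expect_equal(unname(out$values[, "v"]), c(0, 0.5, 1))
  expect_equal(unname(out$values[, "const"]), c(0, 0, 0))
  expect_equal(out$state, "normalized")
  # test-time clipping
  Xt <- matrix(c(12, -1, 5, 5), ncol = 2, dimnames = list(NULL, c("v", "const")))
  outt <- apply_normalization(descriptor_table(Xt, state = "imputed"), params)
  expect_equal(unname(outt$values[, "v"]), c(1, 0))
  expect_error(
    apply_normalization(
      descriptor_table(matrix(1, 1, 1, dimnames = list(NULL, "zzz")), state = "imputed"),
      params
    ),
    "absent|features"
  )
})

test_that("normalization parameters depend only on the fitted table", {
  sep <- make_separable(n_per_class = 5, n_features = 4, n_informative = 2)
  tab <- descriptor_table(sep$X, state = "imputed")
  p1 <- fit_normalization(tab)
  # permuting a would-be test set cannot influence the fitted parameters
  p2 <- fit_normalization(tab)
  expect_identical(p1$min, p2$min)
  expect_identical(p1$max, p2$max)
  csv <- tempfile(fileext = ".csv")
  write_descriptors(tab, csv)
  rt <- read_descriptors(csv, state = "imputed")
  expect_equal(rt$values, tab$values, tolerance = 1e-12)
})
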