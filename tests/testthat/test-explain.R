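# Shapley attribution, importance ranking, feature correlation.

test_that("tree Shapley satisfies local accuracy on a fitted forest", {
  sep <- make_separable(n_per_class = 30, n_features = 5, n_informative = 3, shift = 2)
  mod <- train(classifier_spec("random_forest", n_trees = 15, seed = 3), sep$X, sep$y)
  Xq <- sep$X[seq(1, 120, by = 17), , drop = FALSE]
  for (cl in c("bitter", "umami")) {
    phi <- shapley_values(mod, Xq, cl, background = sep$X)
    pred <- predict_proba(mod, Xq)[, cl]
    expect_true(all(abs(attr(phi, "base_value") + rowSums(phi) - pred) < 1e-6))
    expect_equal(attr(phi, "method"), "treeshap")
  }
})

test_that("a depth-1 tree matches the two-permutation enumeration oracle", {
  set.seed(12)
  X <- matrix(runif(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(ifelse(X[, 1] > 0.55, "pos", "neg"))
  fit <- ranger::ranger(
    x = X, y = y, num.trees = 1, probability = TRUE,
    seed = 8, num.threads = 1, max.depth = 1
  )
  spec <- classifier_spec("random_forest", n_trees = 1, seed = 8)
  mod <- structure(
    list(spec = spec, fit = fit, classes = levels(y), features = colnames(X),
      complexity = 1L),
    class = "taste_model"
  )
  ti <- ranger::treeInfo(fit, 1)
  skip_if(all(ti$terminal), "degenerate single-leaf tree")
  svar <- ti$splitvarName[1]; sval <- ti$splitval[1]
  nL <- sum(X[, svar] <= sval); nR <- nrow(X) - nL
  vL <- ti[ti$nodeID == ti$leftChild[1], "pred.pos"]
  vR <- ti[ti$nodeID == ti$rightChild[1], "pred.pos"]
  for (r in c(1, 7, 50)) {
    x <- X[r, ]
    fx <- if (x[svar] <= sval) vL else vR
    ef <- (nL * vL + nR * vR) / (nL + nR)
    # enumeration over both feature orderings: the split feature gets the
    # full deviation from the cover-weighted expectation, the other gets 0
    oracle <- c(a = 0, b = 0)
    oracle[svar] <- fx - ef
    phi <- shapley_values(mod, X[r, , drop = FALSE], "pos", background = X)
    expect_equal(unname(phi[1, ]), unname(oracle[colnames(X)]), tolerance = 1e-8)
    expect_equal(attr(phi, "base_value"), ef, tolerance = 1e-8)
  }
})

test_that("a constant (single-leaf) tree attributes nothing", {
  set.seed(2)
  X <- matrix(runif(80), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep(c("pos", "neg"), 20))
  fit <- ranger::ranger(x = X, y = y, num.trees = 1, probability = TRUE,
    seed = 1, num.threads = 1, min.node.size = 200)
  mod <- structure(
    list(spec = classifier_spec("random_forest", n_trees = 1, seed = 1),
      fit = fit, classes = levels(y), features = colnames(X), complexity = 1L),
    class = "taste_model"
  )
  phi <- shapley_values(mod, X[1:3, ], "pos", background = X)
  expect_true(all(abs(phi) < 1e-12))
})

test_that("duplicated features share attribution on average", {
  set.seed(31)
  base <- runif(160)
  X <- cbind(a = base, b = base, noise = runif(160))
  y <- factor(ifelse(base > 0.5, "pos", "neg"))
  mod <- train(classifier_spec("random_forest", n_trees = 60, seed = 5), X, y)
  phi <- shapley_values(mod, X[seq(1, 160, 10), ], "pos", background = X)
  ta <- mean(abs(phi[, "a"])); tb <- mean(abs(phi[, "b"]))
  expect_lt(abs(ta - tb) / max(ta + tb, 1e-9), 0.35)
  expect_gt(ta + tb, mean(abs(phi[, "noise"])))
})

test_that("the sampling fallback is used and flagged for SVM models", {
  sep <- make_separable(n_per_class = 15, n_features = 3, n_informative = 2, shift = 3)
  mod <- train(classifier_spec("svm", C = 10, gamma = 0.1, seed = 4), sep$X, sep$y)
  phi <- shapley_values(mod, sep$X[1:2, , drop = FALSE], "bitter",
    background = sep$X, n_perm = 8)
  expect_equal(attr(phi, "method"), "permutation_sampling")
  expect_equal(dim(phi), c(2, 3))
})

test_that("feature ranking averages absolute attributions with stated tie-breaks", {
  z <- matrix(0, 4, 3, dimnames = list(NULL, c("beta", "alpha", "gamma")))
  r0 <- rank_features(list(cl1 = z, cl2 = z))
  expect_equal(r0$importance, rep(0, 3))
  expect_equal(r0$feature, c("alpha", "beta", "gamma"))
  one <- z; one[, "gamma"] <- c(0.2, -0.2, 0.2, -0.2)
  r1 <- rank_features(list(cl1 = one, cl2 = one))
  expect_equal(r1$feature[1], "gamma")
  expect_equal(r1$importance[1], 0.2)
  # hand-computed toy
  a1 <- matrix(c(1, -1, 0.5, 0.5), 2, dimnames = list(NULL, c("u", "v")))
  a2 <- matrix(c(0, 0, 2, 2), 2, dimnames = list(NULL, c("u", "v")))
  rt <- rank_features(list(x = a1, y = a2))
  expect_equal(rt$importance[rt$feature == "u"], mean(c(1, 0)))
  expect_equal(rt$importance[rt$feature == "v"], mean(c(0.5, 2)))
  # sample order does not matter
  rp <- rank_features(list(x = a1[2:1, ], y = a2[2:1, ]))
  expect_identical(rt, rp)
  bad <- matrix(0, 2, 2, dimnames = list(NULL, c("u", "w")))
  expect_error(rank_features(list(a1, bad)), "disagree")
})

test_that("feature correlation matches the covariance formula and flags constants", {
  x <- c(1, 2, 4, 7, 11)
  tab <- cbind(x = x, y2 = 2 * x, yneg = -x, z = c(2, 1, 5, 3, 4), flat = rep(1, 5))
  cm <- feature_correlation(tab)
  expect_equal(unname(diag(cm)[1:4]), rep(1, 4))
  expect_equal(cm["x", "y2"], 1)
  expect_equal(cm["x", "yneg"], -1)
  oracle <- sum((x - mean(x)) * (tab[, "z"] - mean(tab[, "z"]))) /
    sqrt(sum((x - mean(x))^2) * sum((tab[, "z"] - mean(tab[, "z"]))^2))
  expect_equal(cm["x", "z"], oracle, tolerance = 1e-10)
  expect_equal(attr(cm, "flagged"), "flat")
  expect_true(all(cm[!is.na(cm)] >= -1 - 1e-12 & cm[!is.na(cm)] <= 1 + 1e-12))
  expect_error(feature_correlation(tab[1, , drop = FALSE]), "2 samples")
  expect_error(feature_correlation(tab, c("x", "nope")), "unknown")
})
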