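# Metrics, balancing, folds, training, cross-validation.

test_that("metric suite handles perfect, mixed and degenerate predictions", {
  classes <- c("bitter", "sweet", "other", "umami")
  y <- rep(classes, each = 5)
  probs <- matrix(0, 20, 4, dimnames = list(NULL, classes))
  probs[cbind(1:20, match(y, classes))] <- 1
  m <- compute_metrics(y, y, probs)
  expect_equal(unlist(m[c("acc", "f1", "f2", "precision", "recall", "auc")]),
    setNames(rep(1, 6), c("acc", "f1", "f2", "precision", "recall", "auc")))
  # binary toy with precision 0.5, recall 1: F2 = 5*0.5*1/(4*0.5+1)
  yt <- c("bitter", "bitter", "sweet", "sweet")
  yp <- c("bitter", "bitter", "bitter", "bitter")
  pr <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 4, 2, dimnames = list(NULL, c("bitter", "sweet")))
  m2 <- compute_metrics(yt, yp, pr)
  expect_equal(m2$per_class$f2[m2$per_class$class == "bitter"], 5 * 0.5 / 3,
    tolerance = 1e-12)
  # single-class truth with constant correct predictions: ACC 1, AUC flagged
  m3 <- compute_metrics(rep("sweet", 4), rep("sweet", 4),
    matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 4, 2, dimnames = list(NULL, c("bitter", "sweet"))))
  expect_equal(m3$acc, 1)
  expect_true("auc_undefined:sweet" %in% m3$flags)
  expect_error(compute_metrics(c("salty"), c("sweet"), pr[1, , drop = FALSE]), "class")
})

test_that("weighted averages respect their bounds and the recall-accuracy identity", {
  set.seed(11)
  classes <- c("bitter", "sweet", "other", "umami")
  for (i in 1:10) {
    y <- sample(classes, 60, replace = TRUE)
    p <- matrix(runif(240), 60, 4, dimnames = list(NULL, classes))
    p <- p / rowSums(p)
    pred <- colnames(p)[max.col(p)]
    m <- compute_metrics(y, pred, p)
    percls <- m$per_class[m$per_class$support > 0, ]
    expect_gte(m$f1 + 1e-12, min(percls$f1))
    expect_lte(m$f1 - 1e-12, max(percls$f1))
    # support-weighted one-vs-rest recall is exactly the accuracy
    expect_equal(m$recall, m$acc, tolerance = 1e-12)
  }
})

test_that("rank AUC matches pROC and behaves at the extremes", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:5) {
    score <- runif(40)
    lab <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    if (!any(lab) || all(lab)) next
    ours <- tastekit:::auc_rank(score, lab)
    ref <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  # perfect indicator scores give AUC 1
  lab <- rep(c(TRUE, FALSE), 10)
  expect_equal(tastekit:::auc_rank(as.numeric(lab), lab), 1)
  # label-independent scores hover at 1/2
  set.seed(4)
  aucs <- replicate(200, tastekit:::auc_rank(runif(30), sample(c(TRUE, FALSE), 30, TRUE)))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.03)
})

test_that("oversampling balances to the majority with flagged synthetic copies", {
  X <- matrix(rnorm(1307 * 2), ncol = 2)
  y <- rep(c("sweet", "bitter", "other", "umami"), c(360, 360, 360, 227))
  b <- balance_oversample(X, y, seed = 5)
  expect_equal(sum(b$synthetic), 133)
  expect_true(all(b$y[b$synthetic] == "umami"))
  expect_equal(as.vector(table(b$y)), rep(360L, 4))
  # already balanced input is unchanged
  Xb <- matrix(rnorm(40), ncol = 2); yb <- rep(c("a", "b"), each = 10)
  bb <- balance_oversample(Xb, yb, seed = 1)
  expect_identical(bb$X, Xb)
  expect_false(any(bb$synthetic))
  # a single-member minority is the only possible copy source
  X1 <- matrix(rnorm(10), ncol = 2)
  b1 <- balance_oversample(X1, c("a", "a", "a", "a", "b"), seed = 2)
  expect_equal(sum(b1$synthetic), 3)
  expect_true(all(b1$X[b1$synthetic, ] == matrix(X1[5, ], 3, 2, byrow = TRUE)))
})

test_that("stratified folds partition the data evenly within classes", {
  y <- rep(c("a", "b", "c", "d"), each = 25)
  f <- stratified_kfold(y, k = 10, seed = 9)
  expect_equal(as.vector(table(f)), rep(10L, 10))
  for (cl in unique(y)) {
    cnt <- table(f[y == cl])
    expect_lte(max(cnt) - min(cnt), 1)
  }
  expect_identical(f, stratified_kfold(y, k = 10, seed = 9))
  expect_error(stratified_kfold(y, k = 1), ">= 2")
  expect_error(stratified_kfold(c("a", "a", "b"), k = 2), "fewer members")
})

test_that("training is seeded and prediction validates its feature set", {
  sep <- make_separable(n_per_class = 25)
  spec <- classifier_spec("random_forest", n_trees = 95, seed = 31)
  m1 <- train(spec, sep$X, sep$y)
  m2 <- train(spec, sep$X, sep$y)
  p1 <- predict_proba(m1, sep$X)
  p2 <- predict_proba(m2, sep$X)
  expect_identical(p1, p2)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-9))
  expect_equal(m1$complexity, 95)
  expect_error(predict_proba(m1, sep$X[, 1:3]), "lacks")
  # SVM route with probability calibration
  ms <- train(classifier_spec("svm", C = 10, gamma = 0.05, seed = 2), sep$X, sep$y)
  ps <- predict_proba(ms, sep$X)
  expect_true(all(abs(rowSums(ps) - 1) < 1e-6))
  expect_gt(ms$complexity, 0)
})

test_that("cross-validation separates signal from chance", {
  sep <- make_separable(n_per_class = 50, n_features = 30, n_informative = 10, shift = 3)
  spec <- classifier_spec("random_forest", n_trees = 60, seed = 1)
  cv <- cross_validate(spec, sep$X, sep$y, k = 10, seed = 13)
  expect_gte(cv$mean[["acc"]], 0.95)
  expect_equal(nrow(cv$folds), 10)
  set.seed(99)
  ysh <- sample(sep$y)
  cvn <- cross_validate(spec, sep$X, ysh, k = 10, seed = 13)
  expect_lt(abs(cvn$mean[["acc"]] - 0.25), 0.10)
})

test_that("synthetic oversampled copies stay out of validation folds", {
  sep <- make_separable(n_per_class = 12, n_features = 6, n_informative = 3)
  X <- sep$X; y <- sep$y
  fold <- stratified_kfold(y, k = 4, seed = 7)
  for (f in sort(unique(fold))) {
    val_ids <- rownames(X)[fold == f]
    bal <- balance_oversample(X[fold != f, , drop = FALSE], y[fold != f], seed = f)
    syn_ids <- rownames(bal$X)[bal$synthetic]
    # synthetic rows are copies of training-portion rows only
    expect_length(intersect(unique(sub("\\.[0-9]+$", "", syn_ids)), val_ids), 0)
  }
})
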