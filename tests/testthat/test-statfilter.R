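# Statistical screening: normality, Kruskal-Wallis, BH, Mann-Whitney, PCA.

test_that("normality diagnostic handles degenerate and non-normal samples", {
  const <- normality_test(rep(2, 10))
  expect_true(is.na(const))
  expect_true(attr(const, "undefined"))
  expect_error(normality_test(c(1, 2)), "at least 3")
  set.seed(7)
  expect_lt(normality_test(runif(500)), 0.01)
})

test_that("Kruskal-Wallis H matches the hand rank-sum oracle", {
  # groups {1,2} vs {3,4}: mean ranks 1.5 and 3.5
  # H = 12/(N(N+1)) * sum(n_i * Rbar_i^2) - 3(N+1) = 0.6*29 - 15 = 2.4
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4, tolerance = 1e-12)
  # identical observations: identical ranks, H = 0
  expect_equal(kruskal_wallis(rep(5, 8), rep(c("a", "b"), 4))$H, 0)
  # permuting labels within a class leaves H unchanged
  set.seed(1)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  h1 <- kruskal_wallis(v, g)$H
  perm <- c(sample(1:10), 11:30)
  h2 <- kruskal_wallis(v[perm], g[perm])$H
  expect_equal(h1, h2)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 classes")
})

test_that("BH adjustment reproduces the stepwise oracle and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand stepwise oracle on a scrambled vector
  p <- c(0.9, 0.001, 0.04, 0.012, 0.3)
  ord <- order(p)
  m <- length(p)
  qs <- p[ord] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  oracle <- numeric(m); oracle[ord] <- pmin(qs, 1)
  expect_equal(bh_adjust(p), oracle, tolerance = 1e-12)
  # the step-down monotonicity cap is idempotent on sorted inputs, and
  # adjusted values never fall below the raw p-values
  cap <- function(x) rev(cummin(rev(x)))
  qs_sorted <- bh_adjust(p)[order(p)]
  expect_equal(cap(qs_sorted), qs_sorted)
  expect_true(all(bh_adjust(p) >= p - 1e-12))
  expect_true(all(diff(qs_sorted) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("screening recovers planted class shifts with near-certain power", {
  ds <- generate_dataset(
    n_per_class = c(bitter = 80, sweet = 80, umami = 80, other = 80),
    n_features = 50, n_informative = 5, shift = 1.5,
    missing_rate = 0, n_sparse_features = 0, seed = 42
  )
  tab <- ds$table
  tab$state <- "normalized" # already complete; state gate only
  rep <- screen_features(tab, ds$labels, q_threshold = 0.05)
  expect_true(all(rep$selected[ds$truth_mask]))
})

test_that("zero-variance features are flagged and never selected", {
  X <- cbind(signal = rnorm(40), flat = rep(1, 40))
  tab <- descriptor_table(X, state = "imputed")
  rep <- screen_features(tab, rep(c("a", "b"), 20))
  expect_equal(rep$flag[rep$feature == "flat"], "zero_variance")
  expect_false(rep$selected[rep$feature == "flat"])
})

test_that("Mann-Whitney one-vs-rest matches the pair-counting oracle", {
  X <- cbind(v = c(1, 2, 3, 4, 5, 6))
  tab <- descriptor_table(X, state = "imputed")
  res <- mann_whitney_ovr(tab, c("a", "a", "a", "b", "b", "b"), top_k = 5)
  # group a entirely below group b: zero pairs with a > b
  expect_equal(res$a$U[1], 0)
  # identical groups: U = n1*n2/2
  X2 <- cbind(v = c(1, 2, 3, 1, 2, 3))
  res2 <- mann_whitney_ovr(descriptor_table(X2, state = "imputed"),
    c("a", "a", "a", "b", "b", "b"))
  expect_equal(res2$a$U[1], 4.5)
  # top_k larger than the feature count returns everything
  expect_equal(nrow(res$a), 1)
})

test_that("PCA projection matches the eigen-decomposition oracle", {
  # exact line in 2D: first component explains everything
  line <- descriptor_table(
    cbind(x = 1:10, y = 2 * (1:10)) * 1.0, state = "imputed"
  )
  p <- pca_project(line, 2)
  expect_equal(p$explained[1], 1)
  expect_true(all(diff(p$explained) <= 1e-12))
  # 5x4 random table vs brute-force covariance eigen-decomposition
  set.seed(9)
  X <- matrix(runif(20), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
  tab <- descriptor_table(X, state = "imputed")
  p2 <- pca_project(tab, 3)
  C <- stats::cov(X)
  eg <- eigen(C, symmetric = TRUE)
  scores_oracle <- scale(X, center = TRUE, scale = FALSE) %*% eg$vectors[, 1:3]
  for (j in 1:3) {
    expect_lt(min(
      max(abs(p2$scores[, j] - scores_oracle[, j])),
      max(abs(p2$scores[, j] + scores_oracle[, j]))
    ), 1e-8)
  }
  expect_lte(sum(p2$explained), 1 + 1e-12)
  expect_error(pca_project(tab, 10), "exceeds")
})

test_that("two-class Kruskal-Wallis agrees with the Mann-Whitney statistic", {
  set.seed(3)
  for (rep_i in 1:5) {
    v <- rnorm(24)
    g <- rep(c("a", "b"), each = 12)
    H <- kruskal_wallis(v, g)$H
    # normal-approximation identity: H equals the squared standardized U
    U <- unname(suppressWarnings(wilcox.test(v[g == "a"], v[g == "b"],
      exact = FALSE, correct = FALSE))$statistic)
    mu <- 12 * 12 / 2
    s2 <- 12 * 12 * 25 / 12
    expect_equal(H, (U - mu)^2 / s2, tolerance = 1e-8)
  }
})
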