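# Classifier training, boosting-style class balancing and stratified
# cross-validation.

#' Specify a classifier
#'
#' @param family `random_forest` or `svm`
#' @param n_trees random-forest tree count (>= 1)
#' @param C,gamma SVM RBF hyperparameters (> 0)
#' @param seed integer seed making the fit deterministic
#' @return a `ClassifierSpec`
#' @export
classifier_spec <- function(family = c("random_forest", "svm"),
                            n_trees = 95L, C = 1, gamma = 0.1, seed = 1L) {
  family <- match.arg(family)
  if (family == "random_forest") tk_assert(n_trees >= 1, "n_trees must be >= 1")
  if (family == "svm") tk_assert(C > 0 && gamma > 0, "C and gamma must be > 0")
  structure(
    list(
      family = family,
      hyperparams = if (family == "random_forest") {
        list(n_trees = as.integer(n_trees))
      } else {
        list(C = C, gamma = gamma, kernel = "radial")
      },
      seed = as.integer(seed)
    ),
    class = "ClassifierSpec"
  )
}

#' Boosting-style oversampling to class balance
#'
#' Minority classes are augmented with synthetic copies (weighted duplication,
#' no interpolation) until every class reaches the majority count. Selection
#' probability is proportional to boosting-style weights: initialized uniform
#' and uprated for the still-deficient minority class at every round.
#'
#' @param X feature matrix
#' @param y class labels
#' @param seed RNG seed
#' @return list `X`, `y`, `synthetic` (logical flag per row)
#' @export
balance_oversample <- function(X, y, seed = 1L) {
  y <- as.character(y)
  counts <- table(y)
  tk_assert(length(counts) >= 2, "need at least 2 classes")
  tk_assert(all(counts > 0), "empty class")
  target <- max(counts)
  set.seed(seed)
  w <- rep(1 / length(y), length(y))
  add_idx <- integer(0)
  repeat {
    cur <- table(c(y, y[add_idx]))
    deficit <- target - cur[names(counts)]
    if (all(deficit == 0)) break
    for (cl in names(counts)[deficit > 0]) {
      members <- which(y == cl)
      w[members] <- w[members] * (1 + deficit[[cl]] / target)
      pick <- if (length(members) == 1) members else {
        sample(members, 1L, prob = w[members])
      }
      add_idx <- c(add_idx, pick)
    }
  }
  list(
    X = rbind(X, X[add_idx, , drop = FALSE]),
    y = c(y, y[add_idx]),
    synthetic = c(rep(FALSE, length(y)), rep(TRUE, length(add_idx)))
  )
}

#' Stratified k-fold assignment
#'
#' @param y class labels
#' @param k number of folds (default 10)
#' @param seed RNG seed
#' @return integer fold id per observation; per-class counts across folds
#'   differ by at most 1
#' @export
stratified_kfold <- function(y, k = 10L, seed = 1L) {
  tk_assert(k >= 2, "k must be >= 2")
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < k)) {
    tk_stop("class '%s' has fewer members (%d) than folds (%d)",
      names(which.min(counts)), min(counts), k)
  }
  set.seed(seed)
  fold <- integer(length(y))
  pos <- 0L # continue the round-robin across classes to balance fold totals
  for (cl in names(counts)) {
    idx <- sample(which(y == cl))
    fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- pos + length(idx)
  }
  fold
}

#' Fit a classifier
#'
#' Random forests via ranger (probability forest); SVMs via e1071 with RBF
#' kernel and pairwise-coupling probability calibration. Deterministic given
#' the spec seed.
#'
#' @param spec a [classifier_spec()]
#' @param X normalized feature matrix restricted to the selected features
#' @param y class labels
#' @return fitted model handle for [predict_proba()]
#' @export
train <- function(spec, X, y) {
  tk_assert(inherits(spec, "ClassifierSpec"), "not a ClassifierSpec")
  y <- factor(as.character(y))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (spec$family == "random_forest") {
    fit <- ranger::ranger(
      x = X, y = y, num.trees = spec$hyperparams$n_trees,
      probability = TRUE, seed = spec$seed, num.threads = 1L
    )
    complexity <- spec$hyperparams$n_trees
  } else {
    set.seed(spec$seed)
    fit <- e1071::svm(
      x = X, y = y, kernel = "radial",
      cost = spec$hyperparams$C, gamma = spec$hyperparams$gamma,
      probability = TRUE
    )
    complexity <- fit$tot.nSV
  }
  structure(
    list(spec = spec, fit = fit, classes = levels(y), features = colnames(X),
         complexity = complexity),
    class = "taste_model"
  )
}

#' Predict class probabilities
#'
#' @param model fitted model from [train()]
#' @param X feature matrix with the model's features
#' @param class_order column order of the returned matrix
#' @return probability matrix, rows summing to 1
#' @export
predict_proba <- function(model, X, class_order = NULL) {
  tk_assert(inherits(model, "taste_model"), "not a fitted taste model")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  missing_f <- setdiff(model$features, colnames(X))
  if (length(missing_f)) {
    tk_stop("feature set at predict time lacks: %s", paste(head(missing_f, 5), collapse = ", "))
  }
  X <- X[, model$features, drop = FALSE]
  if (model$spec$family == "random_forest") {
    probs <- predict(model$fit, data = X, num.threads = 1L)$predictions
  } else {
    pr <- predict(model$fit, X, probability = TRUE)
    probs <- attr(pr, "probabilities")
  }
  probs <- probs[, model$classes, drop = FALSE]
  if (!is.null(class_order)) {
    keep <- intersect(class_order, colnames(probs))
    probs <- probs[, keep, drop = FALSE]
  }
  probs
}

predict_class <- function(probs) colnames(probs)[max.col(probs, ties.method = "first")]

#' Stratified cross-validation with in-fold oversampling
#'
#' For each fold the training portion alone is balanced by
#' [balance_oversample()] (synthetic copies can never reach a validation
#' fold), the classifier is fitted, and the metric suite evaluated on the
#' held-out portion.
#'
#' @param spec a [classifier_spec()]
#' @param X normalized feature matrix (already restricted to candidate
#'   features)
#' @param y class labels
#' @param k folds (default 10)
#' @param seed RNG seed controlling folds, oversampling and fits
#' @param oversample balance the in-fold training data (default TRUE)
#' @return list with `mean`, `sd` (named metric vectors over folds), per-fold
#'   `folds` data.frame, pooled `distance_term`, mean `complexity`
#' @export
cross_validate <- function(spec, X, y, k = 10L, seed = 1L, oversample = TRUE) {
  X <- as.matrix(X)
  y <- as.character(y)
  fold <- stratified_kfold(y, k, seed = derive_seed(seed, 11L))
  metric_names <- c("acc", "f1", "f2", "precision", "recall", "auc")
  fm <- matrix(NA_real_, k, length(metric_names), dimnames = list(NULL, metric_names))
  complexity <- numeric(k)
  pooled_probs <- NULL; pooled_y <- character(0)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (oversample) {
      bal <- balance_oversample(Xtr, ytr, seed = derive_seed(seed, 100L + f))
      Xtr <- bal$X; ytr <- bal$y
    }
    sp <- spec
    sp$seed <- derive_seed(seed, 200L + f)
    model <- train(sp, Xtr, ytr)
    probs <- predict_proba(model, X[te, , drop = FALSE])
    pred <- predict_class(probs)
    mets <- compute_metrics(y[te], pred, probs,
      class_order = union(TASTE_CLASSES, unique(y)))
    fm[f, ] <- unlist(mets[metric_names])
    complexity[f] <- model$complexity
    pooled_probs <- rbind(pooled_probs, probs)
    pooled_y <- c(pooled_y, y[te])
  }
  list(
    mean = colMeans(fm), sd = apply(fm, 2, sd),
    folds = as.data.frame(fm),
    complexity = mean(complexity),
    distance_term = manhattan_score(pooled_y, pooled_probs),
    n_features = ncol(X), k = k
  )
}
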