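# Shapley attribution for the fitted classifiers: exact path-dependent
# TreeSHAP for random forests (per-tree recursion over the split structure
# with training-cover weighting), permutation-sampling Shapley as the fallback
# for non-tree models. Plus global importance ranking and feature correlation.

# --- tree extraction -------------------------------------------------------

# Convert one ranger tree into plain arrays (1-based node ids).
.extract_tree <- function(rf, t, class_names) {
  ti <- ranger::treeInfo(rf, t)
  predcols <- paste0("pred.", class_names)
  list(
    left = ti$leftChild + 1L, right = ti$rightChild + 1L,
    splitvar = ti$splitvarID + 1L, splitval = ti$splitval,
    terminal = ti$terminal,
    values = as.matrix(ti[, predcols, drop = FALSE])
  )
}

# Route rows of X through a tree; returns terminal node id per row.
.route <- function(tree, X) {
  out <- integer(nrow(X))
  for (r in seq_len(nrow(X))) {
    j <- 1L
    while (!tree$terminal[j]) {
      j <- if (X[r, tree$splitvar[j]] <= tree$splitval[j]) tree$left[j] else tree$right[j]
    }
    out[r] <- j
  }
  out
}

# Training-sample counts per node (root to leaves).
.node_covers <- function(tree, X) {
  covers <- numeric(length(tree$terminal))
  for (r in seq_len(nrow(X))) {
    j <- 1L
    covers[j] <- covers[j] + 1
    while (!tree$terminal[j]) {
      j <- if (X[r, tree$splitvar[j]] <= tree$splitval[j]) tree$left[j] else tree$right[j]
      covers[j] <- covers[j] + 1
    }
  }
  covers
}

# --- path-dependent TreeSHAP ----------------------------------------------

.path_extend <- function(path, pz, po, pi) {
  L <- nrow(path)
  path <- rbind(path, data.frame(d = pi, z = pz, o = po, w = if (L == 0) 1 else 0))
  if (L >= 1) {
    for (i in seq(L, 1)) {
      path$w[i + 1] <- path$w[i + 1] + po * path$w[i] * i / (L + 1)
      path$w[i] <- pz * path$w[i] * (L + 1 - i) / (L + 1)
    }
  }
  path
}

.path_unwind_weights <- function(path, i) {
  L <- nrow(path)
  w <- path$w
  nn <- w[L]
  out <- numeric(L - 1)
  if (L >= 2) {
    for (j in seq(L - 1, 1)) {
      if (path$o[i] != 0) {
        t <- w[j]
        out[j] <- nn * L / (j * path$o[i])
        nn <- t - out[j] * path$z[i] * (L - j) / L
      } else {
        out[j] <- w[j] * L / (path$z[i] * (L - j))
      }
    }
  }
  out
}

.path_unwind <- function(path, i) {
  w <- .path_unwind_weights(path, i)
  L <- nrow(path)
  if (i <= L - 1) {
    path$d[i:(L - 1)] <- path$d[(i + 1):L]
    path$z[i:(L - 1)] <- path$z[(i + 1):L]
    path$o[i:(L - 1)] <- path$o[(i + 1):L]
  }
  path <- path[seq_len(L - 1), , drop = FALSE]
  path$w <- w
  path
}

# SHAP values of one tree for one sample and one output column.
.treeshap_one <- function(tree, covers, x, value_col, n_features) {
  phi <- numeric(n_features)
  recurse <- function(j, path, pz, po, pi) {
    path <- .path_extend(path, pz, po, pi)
    if (tree$terminal[j]) {
      L <- nrow(path)
      if (L >= 2) {
        for (i in 2:L) {
          w <- sum(.path_unwind_weights(path, i))
          phi[path$d[i]] <<- phi[path$d[i]] +
            w * (path$o[i] - path$z[i]) * tree$values[j, value_col]
        }
      }
      return(invisible())
    }
    sv <- tree$splitvar[j]
    hot <- if (x[sv] <= tree$splitval[j]) tree$left[j] else tree$right[j]
    cold <- if (hot == tree$left[j]) tree$right[j] else tree$left[j]
    iz <- 1; io <- 1
    k <- which(path$d == sv & seq_len(nrow(path)) > 1)
    if (length(k)) {
      k <- k[1]
      iz <- path$z[k]; io <- path$o[k]
      path <- .path_unwind(path, k)
    }
    recurse(hot, path, iz * covers[hot] / covers[j], io, sv)
    recurse(cold, path, iz * covers[cold] / covers[j], 0, sv)
  }
  empty <- data.frame(d = integer(0), z = numeric(0), o = numeric(0), w = numeric(0))
  recurse(1L, empty, 1, 1, 0L)
  phi
}

# --- public API ------------------------------------------------------------

#' Shapley feature attributions for a fitted taste model
#'
#' For random forests: exact path-dependent tree Shapley values computed from
#' the forest's split structure and training covers, averaged over trees, for
#' the probability of the chosen class. Local accuracy holds: base value plus
#' the row sum equals the predicted class probability. For non-tree models a
#' seeded permutation-sampling approximation is used and flagged.
#'
#' @param model fitted model from [train()] (or a `TastePredictor`)
#' @param X matrix of samples to explain (model features)
#' @param class_name class whose predicted probability is attributed
#' @param background training matrix used as reference distribution (covers
#'   for trees, marginal imputation for the sampling fallback)
#' @param n_perm permutations for the sampling fallback
#' @return attribution matrix (samples x features) with attributes
#'   `base_value` and `method`
#' @export
shapley_values <- function(model, X, class_name, background, n_perm = 64L) {
  if (inherits(model, "TastePredictor")) {
    if (missing(background)) background <- model$train_X
    model <- model$model
  }
  tk_assert(inherits(model, "taste_model"), "not a fitted taste model")
  tk_assert(class_name %in% model$classes, "unknown class '%s'", class_name)
  X <- as.matrix(X)[, model$features, drop = FALSE]
  background <- as.matrix(background)[, model$features, drop = FALSE]
  nf <- length(model$features)

  if (model$spec$family == "random_forest") {
    value_col <- match(class_name, model$classes)
    ntree <- model$spec$hyperparams$n_trees
    phi <- matrix(0, nrow(X), nf, dimnames = list(rownames(X), model$features))
    base <- 0
    for (t in seq_len(ntree)) {
      tree <- .extract_tree(model$fit, t, model$classes)
      covers <- .node_covers(tree, background)
      base <- base + sum(
        covers[tree$terminal] / covers[1] * tree$values[tree$terminal, value_col]
      )
      for (r in seq_len(nrow(X))) {
        phi[r, ] <- phi[r, ] + .treeshap_one(tree, covers, X[r, ], value_col, nf)
      }
    }
    phi <- phi / ntree
    attr(phi, "base_value") <- base / ntree
    attr(phi, "method") <- "treeshap"
    return(phi)
  }

  # permutation-sampling fallback (flagged)
  set.seed(model$spec$seed)
  pred1 <- function(M) predict_proba(model, M)[, class_name]
  base <- mean(pred1(background))
  phi <- matrix(0, nrow(X), nf, dimnames = list(rownames(X), model$features))
  nb <- nrow(background)
  for (r in seq_len(nrow(X))) {
    acc <- numeric(nf)
    for (p in seq_len(n_perm)) {
      ord <- sample.int(nf)
      b <- background[sample.int(nb, 1), ]
      cur <- b
      prev <- pred1(matrix(cur, 1, dimnames = list(NULL, model$features)))
      for (f in ord) {
        cur[f] <- X[r, f]
        now <- pred1(matrix(cur, 1, dimnames = list(NULL, model$features)))
        acc[f] <- acc[f] + (now - prev)
        prev <- now
      }
    }
    phi[r, ] <- acc / n_perm
  }
  attr(phi, "base_value") <- base
  attr(phi, "method") <- "permutation_sampling"
  phi
}

#' Global feature ranking from per-class attributions
#'
#' Importance of a feature is the mean over classes of the mean absolute
#' Shapley value; features are returned in descending importance with
#' alphabetical tie-break.
#'
#' @param attributions named list (one attribution matrix per class, same
#'   features and samples)
#' @return data.frame `feature, importance, rank`
#' @export
rank_features <- function(attributions) {
  tk_assert(length(attributions) >= 1, "no attributions")
  feats <- colnames(attributions[[1]])
  same <- vapply(attributions, function(a) identical(colnames(a), feats), TRUE)
  tk_assert(all(same), "attribution matrices disagree on features")
  imp <- rowMeans(vapply(attributions, function(a) colMeans(abs(a)), numeric(length(feats))))
  ord <- order(-imp, feats)
  data.frame(
    feature = feats[ord], importance = unname(imp[ord]),
    rank = seq_along(feats), stringsAsFactors = FALSE
  )
}

#' Pearson correlation matrix of selected features
#'
#' @param table a DescriptorTable (any state) or numeric matrix
#' @param feature_subset features to correlate (default: all)
#' @return symmetric correlation matrix; zero-variance features yield NA
#'   entries and are reported in `attr(,"flagged")`
#' @export
feature_correlation <- function(table, feature_subset = NULL) {
  X <- if (inherits(table, "DescriptorTable")) table$values else as.matrix(table)
  tk_assert(nrow(X) >= 2, "need at least 2 samples")
  if (!is.null(feature_subset)) {
    missing_f <- setdiff(feature_subset, colnames(X))
    tk_assert(length(missing_f) == 0, "unknown feature(s): %s",
      paste(head(missing_f, 5), collapse = ", "))
    X <- X[, feature_subset, drop = FALSE]
  }
  novar <- apply(X, 2, function(v) var(v, na.rm = TRUE) == 0 || all(is.na(v)))
  cm <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  diag(cm)[!novar] <- 1
  attr(cm, "flagged") <- colnames(X)[novar]
  cm
}
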