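# Non-parametric screening of descriptors across taste classes.

#' Shapiro-Wilk normality diagnostic
#'
#' Used to justify non-parametric class comparisons; its result never gates
#' feature selection. Constant samples return NA with an `undefined` flag
#' (treated as non-normal downstream).
#'
#' @param values numeric sample, 3 <= n <= 5000
#' @return p-value, or NA with attribute `undefined = TRUE` for degenerate
#'   samples
#' @export
normality_test <- function(values) {
  values <- values[!is.na(values)]
  tk_assert(length(values) >= 3, "need at least 3 observations")
  if (length(unique(values)) == 1) {
    return(structure(NA_real_, undefined = TRUE))
  }
  if (length(values) > 5000) values <- values[seq_len(5000)]
  shapiro.test(values)$p.value
}

#' Kruskal-Wallis rank test across classes
#'
#' Rank-based H with tie correction; p-value from the chi-square distribution
#' with (number of classes - 1) degrees of freedom.
#'
#' @param values numeric vector
#' @param class_labels class membership, at least 2 non-empty classes
#' @return list with `H` and `p`
#' @export
kruskal_wallis <- function(values, class_labels) {
  class_labels <- as.factor(as.character(class_labels))
  tk_assert(nlevels(class_labels) >= 2, "need at least 2 classes")
  tk_assert(all(table(class_labels) > 0), "each class must be non-empty")
  if (length(unique(values[!is.na(values)])) == 1) {
    return(list(H = 0, p = 1)) # identical ranks everywhere
  }
  kt <- kruskal.test(values, class_labels)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values), capped at 1, returned in the input
#' order.
#'
#' @param p_values numeric vector of p-values in [0,1]
#' @return vector of q-values
#' @export
bh_adjust <- function(p_values) {
  tk_assert(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), "p-values must lie in [0,1]")
  p.adjust(p_values, method = "BH")
}

#' Screen features by Kruskal-Wallis with FDR control
#'
#' Per-feature Kruskal-Wallis across the taste classes, Benjamini-Hochberg
#' correction, and selection at `q < q_threshold`. Zero-variance features are
#' flagged and never selected.
#'
#' @param table a normalized DescriptorTable
#' @param labels class labels aligned with the table rows
#' @param q_threshold FDR threshold (default 0.05)
#' @return data.frame with columns `feature`, `normality_p`, `H`, `p`, `q`,
#'   `selected`, `flag`
#' @export
screen_features <- function(table, labels, q_threshold = 0.05) {
  tk_assert(inherits(table, "DescriptorTable"), "not a DescriptorTable")
  X <- table$values
  tk_assert(nrow(X) == length(labels), "labels must match table rows")
  labels <- as.factor(as.character(labels))
  res <- data.frame(
    feature = colnames(X), normality_p = NA_real_, H = NA_real_,
    p = NA_real_, q = NA_real_, selected = FALSE, flag = "",
    stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (length(unique(v[!is.na(v)])) <= 1) {
      res$flag[j] <- "zero_variance"
      next
    }
    res$normality_p[j] <- tryCatch(as.numeric(normality_test(v)), error = function(e) NA_real_)
    kw <- kruskal_wallis(v, labels)
    res$H[j] <- kw$H
    res$p[j] <- kw$p
  }
  ok <- !is.na(res$p)
  res$q[ok] <- bh_adjust(res$p[ok])
  res$selected <- !is.na(res$q) & res$q < q_threshold
  attr(res, "summary") <- sprintf(
    "%d of %d features selected at q < %g", sum(res$selected), nrow(res), q_threshold
  )
  res
}

#' Mann-Whitney one-vs-rest feature ranking per class
#'
#' For every class, each feature is compared between that class and the
#' pooled rest with the two-sided Mann-Whitney (Wilcoxon rank-sum) test;
#' features are ranked by ascending p-value and the top `top_k` reported
#' (heatmap-ready). P-values are reported unadjusted.
#'
#' @param table a normalized DescriptorTable
#' @param labels class labels
#' @param top_k features to report per class
#' @return named list (per class) of data.frames `feature,U,p`
#' @export
mann_whitney_ovr <- function(table, labels, top_k = 5L) {
  X <- table$values
  labels <- as.factor(as.character(labels))
  tk_assert(all(table(labels) > 0), "empty class")
  out <- list()
  for (cl in levels(labels)) {
    inc <- labels == cl
    tk_assert(any(inc) && any(!inc), "class '%s' empty or exhaustive", cl)
    U <- p <- rep(NA_real_, ncol(X))
    for (j in seq_len(ncol(X))) {
      v <- X[, j]
      if (length(unique(v[!is.na(v)])) <= 1) next
      wt <- suppressWarnings(wilcox.test(v[inc], v[!inc], exact = FALSE))
      U[j] <- unname(wt$statistic)
      p[j] <- wt$p.value
    }
    df <- data.frame(feature = colnames(X), U = U, p = p, stringsAsFactors = FALSE)
    df <- df[order(df$p), , drop = FALSE]
    rownames(df) <- NULL
    out[[cl]] <- head(df, min(top_k, nrow(df)))
  }
  out
}

#' Principal component projection
#'
#' Centered (not rescaled) PCA of the normalized table; components ordered by
#' decreasing explained variance.
#'
#' @param table a normalized DescriptorTable
#' @param n_components number of components to return
#' @return list with `scores` (n x n_components), `explained` (variance
#'   fractions) and the `rotation` matrix
#' @export
pca_project <- function(table, n_components = 3L) {
  X <- table$values
  tk_assert(
    n_components <= min(nrow(X), ncol(X)),
    "n_components exceeds min(rows, features)"
  )
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = pc$x[, seq_len(n_components), drop = FALSE],
    explained = expl[seq_len(n_components)],
    rotation = pc$rotation[, seq_len(n_components), drop = FALSE]
  )
}
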