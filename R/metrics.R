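# The multi-class metric suite: accuracy, support-weighted one-vs-rest
# F1/F2/precision/recall, and one-vs-rest AUC.

# Rank-statistic AUC (equivalent to the Mann-Whitney U / (n1*n0) estimator,
# average ranks under ties). Used in the evolutionary inner loop for speed;
# cross-checked against pROC in the test suite.
auc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

fbeta <- function(precision, recall, beta) {
  denom <- beta^2 * precision + recall
  ifelse(denom > 0, (1 + beta^2) * precision * recall / denom, 0)
}

#' Compute the multi-class metric suite
#'
#' Accuracy is the overall fraction correct. F1, F2, precision and recall are
#' one-vs-rest per class and averaged weighted by class support (which makes
#' the weighted recall equal the accuracy). AUC is one-vs-rest per class on
#' the predicted class probabilities, support-weighted over classes where it
#' is defined; degenerate classes are flagged.
#'
#' @param y_true true class labels
#' @param y_pred predicted class labels
#' @param probs matrix of class probabilities, columns named by class
#' @param class_order class order used for reporting (default
#'   bitter, sweet, other, umami)
#' @return list with overall metrics, a `per_class` data.frame and `flags`
#' @export
compute_metrics <- function(y_true, y_pred, probs, class_order = TASTE_CLASSES) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  bad <- setdiff(unique(y_true), class_order)
  if (length(bad)) tk_stop("class(es) not in class_order: %s", paste(bad, collapse = ", "))
  tk_assert(is.matrix(probs) && !is.null(colnames(probs)), "probs must be a named matrix")
  tk_assert(
    all(abs(rowSums(probs) - 1) < 1e-6),
    "probability rows must sum to 1"
  )
  n <- length(y_true)
  flags <- character(0)
  per <- data.frame(
    class = class_order, support = NA_real_, precision = NA_real_,
    recall = NA_real_, f1 = NA_real_, f2 = NA_real_, auc = NA_real_,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(class_order)) {
    cl <- class_order[k]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    per$support[k] <- sum(y_true == cl)
    per$precision[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$recall[k] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    per$f1[k] <- fbeta(per$precision[k], per$recall[k], 1)
    per$f2[k] <- fbeta(per$precision[k], per$recall[k], 2)
    if (cl %in% colnames(probs)) {
      per$auc[k] <- auc_rank(probs[, cl], y_true == cl)
      if (per$support[k] > 0 && is.na(per$auc[k])) {
        flags <- c(flags, sprintf("auc_undefined:%s", cl))
      }
    }
  }
  w <- per$support / n
  wavg <- function(x) {
    ok <- !is.na(x) & per$support > 0
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * w[ok]) / sum(w[ok])
  }
  list(
    acc = mean(y_true == y_pred),
    f1 = wavg(per$f1), f2 = wavg(per$f2),
    precision = wavg(per$precision), recall = wavg(per$recall),
    auc = wavg(per$auc),
    per_class = per, flags = flags
  )
}

# Manhattan-distance objective: 1 - (mean L1 distance between predicted
# probability vectors and one-hot truths)/2; a [0,1] maximization score.
manhattan_score <- function(y_true, probs) {
  onehot <- matrix(0, length(y_true), ncol(probs), dimnames = list(NULL, colnames(probs)))
  onehot[cbind(seq_along(y_true), match(y_true, colnames(probs)))] <- 1
  1 - mean(rowSums(abs(probs - onehot))) / 2
}
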