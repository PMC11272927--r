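# Missing-value handling and normalization of descriptor tables.

#' Drop features with a high fraction of missing values
#'
#' Removes every feature whose missing fraction strictly exceeds
#' `max_missing_fraction` (default 30%).
#'
#' @param table a raw DescriptorTable
#' @param max_missing_fraction threshold on the per-feature missing fraction
#' @return filtered DescriptorTable; dropped names in `attr(,"dropped")`
#' @export
drop_sparse_features <- function(table, max_missing_fraction = 0.30) {
  tk_assert(inherits(table, "DescriptorTable"), "not a DescriptorTable")
  frac <- colMeans(is.na(table$values))
  drop <- frac > max_missing_fraction
  if (all(drop)) tk_stop("all features exceed the missing-value threshold")
  out <- descriptor_table(
    table$values[, !drop, drop = FALSE],
    state = "filtered",
    log = c(table$log, sprintf(
      "dropped %d/%d features with missing fraction > %.0f%%",
      sum(drop), length(drop), 100 * max_missing_fraction
    ))
  )
  attr(out, "dropped") <- names(frac)[drop]
  out
}

#' k-nearest-neighbour imputation of missing descriptor values
#'
#' Each missing cell is replaced by the mean of that feature over the k rows
#' nearest in Euclidean distance, computed on the mutually observed features
#' after mean scaling. k is capped at the number of eligible rows. Observed
#' cells are left untouched.
#'
#' @param table a filtered DescriptorTable
#' @param k neighbourhood size (default 20)
#' @return imputed DescriptorTable with no missing values
#' @export
knn_impute <- function(table, k = 20L) {
  tk_assert(inherits(table, "DescriptorTable"), "not a DescriptorTable")
  X <- table$values
  n <- nrow(X)
  all_missing_row <- rowSums(!is.na(X)) == 0
  if (any(all_missing_row)) {
    tk_stop("row(s) with all features missing: %s",
      paste(rownames(X)[all_missing_row], collapse = ", "))
  }
  # drop features observed nowhere (cannot be imputed from data)
  dead <- colSums(!is.na(X)) == 0
  X <- X[, !dead, drop = FALSE]
  if (anyNA(X)) {
    colmu <- colMeans(X, na.rm = TRUE)
    scl <- ifelse(abs(colmu) > 0, abs(colmu), 1)
    Xs <- sweep(X, 2, scl, "/")
    obs <- !is.na(Xs)
    for (i in which(rowSums(is.na(X)) > 0)) {
      others <- setdiff(seq_len(n), i)
      d2 <- vapply(others, function(j) {
        sh <- obs[i, ] & obs[j, ]
        if (!any(sh)) return(Inf)
        sum((Xs[i, sh] - Xs[j, sh])^2) / sum(sh)
      }, numeric(1))
      ord <- others[order(d2)]
      for (f in which(is.na(X[i, ]))) {
        cand <- ord[obs[ord, f] & is.finite(d2[order(d2)])]
        if (length(cand) == 0) {
          X[i, f] <- colmu[f]
        } else {
          kk <- min(k, length(cand))
          X[i, f] <- mean(X[cand[seq_len(kk)], f])
        }
      }
    }
  }
  descriptor_table(X,
    state = "imputed",
    log = c(table$log, sprintf("kNN imputation with k = %d", k))
  )
}

#' Fit min-max normalization parameters
#'
#' @param table an imputed DescriptorTable
#' @param fitted_on label recorded for provenance
#' @return a `NormalizationParams` object (per-feature min and max)
#' @export
fit_normalization <- function(table, fitted_on = "train") {
  tk_assert(inherits(table, "DescriptorTable"), "not a DescriptorTable")
  tk_assert(!anyNA(table$values), "impute before fitting normalization")
  structure(
    list(
      feature_names = table$features,
      min = apply(table$values, 2, min),
      max = apply(table$values, 2, max),
      fitted_on = fitted_on
    ),
    class = "NormalizationParams"
  )
}

#' Apply min-max normalization to [0,1]
#'
#' x' = (x - min)/(max - min); constant features map to 0; values outside the
#' fitted range (e.g., test compounds) are clipped into [0,1].
#'
#' @param table an imputed DescriptorTable
#' @param params NormalizationParams fitted on the training table
#' @return normalized DescriptorTable
#' @export
apply_normalization <- function(table, params) {
  tk_assert(inherits(params, "NormalizationParams"), "not NormalizationParams")
  unknown <- setdiff(params$feature_names, table$features)
  if (length(unknown)) {
    tk_stop("features absent from table: %s", paste(head(unknown, 5), collapse = ", "))
  }
  X <- table$values[, params$feature_names, drop = FALSE]
  rng <- params$max - params$min
  Xn <- sweep(X, 2, params$min, "-")
  Xn <- sweep(Xn, 2, ifelse(rng > 0, rng, 1), "/")
  Xn[, rng == 0] <- 0
  Xn[Xn < 0] <- 0
  Xn[Xn > 1] <- 1
  descriptor_table(Xn,
    state = "normalized",
    log = c(table$log, sprintf("min-max normalized against '%s' parameters", params$fitted_on))
  )
}
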