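# The frozen final model: selected features, fitted normalization, fitted
# classifier, training references for explanation and applicability scoring.

#' Build a taste predictor from an imputed training table
#'
#' Fits the min-max normalization on the training table, restricts to the
#' selected features, fits the classifier, and freezes everything (plus the
#' training matrix as Shapley background and, when training SMILES are given,
#' the training fingerprints for applicability scoring) into a portable
#' bundle.
#'
#' @param table imputed (or normalized) training DescriptorTable
#' @param labels taste labels aligned with the table rows
#' @param selected_features feature names the model uses
#' @param spec a [classifier_spec()]
#' @param train_smiles optional canonical SMILES of the training compounds
#'   (enables applicability scoring at prediction time)
#' @param cv optional cross-validation summary stored as provenance
#' @return a `TastePredictor`
#' @export
build_predictor <- function(table, labels, selected_features, spec,
                            train_smiles = NULL, cv = NULL) {
  tk_assert(inherits(table, "DescriptorTable"), "not a DescriptorTable")
  missing_f <- setdiff(selected_features, table$features)
  tk_assert(length(missing_f) == 0, "unknown feature(s): %s",
    paste(head(missing_f, 5), collapse = ", "))
  if (table$state == "normalized") {
    norm <- fit_normalization(table, fitted_on = "train(pre-normalized)")
    Xn <- table$values
  } else {
    norm <- fit_normalization(table)
    Xn <- apply_normalization(table, norm)$values
  }
  Xsel <- Xn[, selected_features, drop = FALSE]
  model <- train(spec, Xsel, labels)
  fps <- NULL
  if (!is.null(train_smiles)) {
    fps <- morgan_fingerprint(train_smiles)
  }
  structure(
    list(
      schema_version = 1L,
      selected_features = selected_features,
      normalization = norm,
      spec = spec,
      model = model,
      class_order = TASTE_CLASSES,
      train_X = Xsel,
      train_labels = as.character(labels),
      train_fps = fps,
      cv = cv,
      metadata = list(
        created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
        package_version = as.character(packageVersion("tastekit"))
      )
    ),
    class = "TastePredictor"
  )
}

#' @export
print.TastePredictor <- function(x, ...) {
  cat(sprintf(
    "TastePredictor: %s on %d features (classes: %s)\n",
    x$spec$family, length(x$selected_features),
    paste(x$class_order, collapse = ", ")
  ))
  invisible(x)
}

#' Predict taste classes for new descriptor rows
#'
#' Applies the frozen normalization (clipping out-of-range values into
#' [0,1]), restricts to the selected features and returns per-class
#' probabilities over the fixed class order (bitter, sweet, other, umami).
#'
#' @param predictor a `TastePredictor`
#' @param table DescriptorTable (raw or imputed) of the query compounds;
#'   missing values in the selected features are imputed from the training
#'   feature means
#' @return data.frame: `id`, `predicted`, one probability column per class
#' @export
predict_taste <- function(predictor, table) {
  tk_assert(inherits(predictor, "TastePredictor"), "not a TastePredictor")
  tk_assert(inherits(table, "DescriptorTable"), "not a DescriptorTable")
  missing_f <- setdiff(predictor$selected_features, table$features)
  tk_assert(length(missing_f) == 0, "query table lacks feature(s): %s",
    paste(head(missing_f, 5), collapse = ", "))
  X <- table$values[, predictor$normalization$feature_names, drop = FALSE]
  # fall back to the training mean (mid-range after normalization) per cell
  if (anyNA(X)) {
    mid <- (predictor$normalization$min + predictor$normalization$max) / 2
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- mid[j]
    }
  }
  tmp <- descriptor_table(X, state = "imputed")
  Xn <- apply_normalization(tmp, predictor$normalization)$values
  probs <- predict_proba(predictor$model,
    Xn[, predictor$selected_features, drop = FALSE])
  ord <- intersect(predictor$class_order, colnames(probs))
  probs <- probs[, ord, drop = FALSE]
  data.frame(
    id = table$ids,
    predicted = predict_class(probs),
    probs,
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

#' Save / load a predictor bundle
#'
#' Single-file serialized bundle with a schema version check on load.
#' @param predictor a `TastePredictor`
#' @param path bundle file path
#' @export
save_predictor <- function(predictor, path) {
  tk_assert(inherits(predictor, "TastePredictor"), "not a TastePredictor")
  saveRDS(predictor, path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  tk_assert(file.exists(path), "model bundle not found: %s", path)
  p <- readRDS(path)
  tk_assert(
    inherits(p, "TastePredictor") && identical(p$schema_version, 1L),
    "unreadable or incompatible model bundle"
  )
  p
}
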