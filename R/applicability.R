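# Applicability-domain scoring: circular (Morgan-type) fingerprints, Tanimoto
# similarity to the training chemical space, and similarity-stratified
# performance.

#' Circular substructure fingerprints
#'
#' Hashed circular fingerprints of the stated radius (default 2, the ECFP4
#' neighbourhood), folded by OR to `n_bits` bits.
#'
#' @param smiles character vector of valid standardized SMILES
#' @param n_bits fingerprint length (default 1024)
#' @param radius circular neighbourhood radius (default 2)
#' @return binary matrix (molecules x bits)
#' @export
morgan_fingerprint <- function(smiles, n_bits = 1024L, radius = 2L) {
  tk_assert(length(smiles) >= 1, "no SMILES")
  ok <- !is.na(canonicalize_smiles(smiles))
  if (!all(ok)) {
    tk_stop("invalid SMILES: %s", paste(head(smiles[!ok], 5), collapse = ", "))
  }
  fpname <- paste0("ECFP", 2L * radius)
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
  raw <- ChemmineOB::fingerprint_OB(mols, fpname)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
  width <- ncol(raw)
  tk_assert(width %% n_bits == 0, "n_bits must divide the native width %d", width)
  folds <- width / n_bits
  out <- matrix(0L, nrow(raw), n_bits)
  for (f in seq_len(folds)) {
    out <- pmax(out, raw[, ((f - 1) * n_bits + 1):(f * n_bits), drop = FALSE] > 0)
  }
  mode(out) <- "integer"
  rownames(out) <- names(smiles)
  out
}

#' Tanimoto similarity of two bit vectors
#'
#' |a AND b| / |a OR b|; defined as 0 when both vectors are empty.
#' @param a,b binary vectors of equal length
#' @return similarity in [0,1]
#' @export
tanimoto <- function(a, b) {
  tk_assert(length(a) == length(b), "fingerprint length mismatch")
  a <- a > 0; b <- b > 0
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

# All-pairs Tanimoto between two fingerprint matrices (rows = molecules).
tanimoto_matrix <- function(A, B) {
  A <- (A > 0) * 1; B <- (B > 0) * 1
  inter <- A %*% t(B)
  na <- rowSums(A); nb <- rowSums(B)
  un <- outer(na, nb, "+") - inter
  out <- ifelse(un > 0, inter / un, 0)
  out
}

#' Mean similarity to the k most similar training compounds
#'
#' @param query_fp one fingerprint (vector) or matrix of query fingerprints
#' @param train_fps training fingerprint matrix (non-empty)
#' @param k neighbours to average (default 5; capped at the training size)
#' @param exclude_identical drop neighbours with an identical fingerprint
#'   (used when scoring training compounds against their own set)
#' @return numeric vector of average top-k similarities in [0,1]
#' @export
avg_topk_similarity <- function(query_fp, train_fps, k = 5L, exclude_identical = FALSE) {
  if (is.null(dim(query_fp))) query_fp <- matrix(query_fp, nrow = 1)
  tk_assert(!is.null(dim(train_fps)) && nrow(train_fps) > 0, "empty training fingerprint set")
  S <- tanimoto_matrix(query_fp, train_fps)
  vapply(seq_len(nrow(S)), function(i) {
    s <- S[i, ]
    if (exclude_identical) {
      ident <- apply(train_fps, 1, function(tf) all((tf > 0) == (query_fp[i, ] > 0)))
      s <- s[!ident]
      if (length(s) == 0) return(NA_real_)
    }
    mean(sort(s, decreasing = TRUE)[seq_len(min(k, length(s)))])
  }, numeric(1))
}

#' Model performance stratified by applicability score
#'
#' Bins compounds into `n_bins` equal-frequency (quantile) bins of the
#' similarity score and evaluates the metric suite in each bin. Duplicate
#' quantile edges are merged (bin count reduced and flagged).
#'
#' @param predictions predicted class labels
#' @param truths true class labels
#' @param scores applicability scores (e.g. [avg_topk_similarity()])
#' @param n_bins number of similarity bins (default 10)
#' @return data.frame of per-bin metrics with attribute `merged_bins`
#' @export
performance_by_similarity <- function(predictions, truths, scores, n_bins = 10L) {
  n <- length(scores)
  tk_assert(length(predictions) == n && length(truths) == n, "length mismatch")
  tk_assert(n >= n_bins, "fewer samples than bins")
  edges <- quantile(scores, probs = seq(0, 1, length.out = n_bins + 1), names = FALSE)
  uedges <- unique(edges)
  merged <- length(uedges) < length(edges)
  if (length(uedges) < 2) {
    bin <- rep(1L, n)
    nb <- 1L
  } else {
    bin <- findInterval(scores, uedges, all.inside = TRUE)
    nb <- length(uedges) - 1L
  }
  classes <- union(TASTE_CLASSES, union(unique(truths), unique(predictions)))
  rows <- lapply(seq_len(nb), function(b) {
    sel <- bin == b
    acc <- mean(predictions[sel] == truths[sel])
    data.frame(
      bin = b, n = sum(sel),
      score_lo = min(scores[sel]), score_hi = max(scores[sel]),
      acc = acc
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "merged_bins") <- merged
  out
}
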