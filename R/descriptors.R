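# DescriptorTable container and the descriptor computation front end.

#' Construct a descriptor table
#'
#' @param values numeric matrix, rows = compounds (rownames = ids),
#'   columns = named features; `NA` marks a failed/missing computation
#' @param state processing state, one of `raw`, `filtered`, `imputed`,
#'   `normalized`
#' @param log character vector of provenance messages
#' @return a `DescriptorTable` object
#' @export
descriptor_table <- function(values, state = "raw", log = character(0)) {
  tk_assert(is.matrix(values), "values must be a matrix")
  tk_assert(!is.null(colnames(values)), "values must have feature names")
  tk_assert(!anyDuplicated(colnames(values)), "feature names must be unique")
  if (is.null(rownames(values))) rownames(values) <- paste0("cmpd", seq_len(nrow(values)))
  state <- match.arg(state, c("raw", "filtered", "imputed", "normalized"))
  if (state == "normalized") {
    tk_assert(!anyNA(values), "normalized table may not contain missing values")
    tk_assert(all(values >= 0 & values <= 1), "normalized values must lie in [0,1]")
  }
  structure(
    list(
      ids = rownames(values), features = colnames(values),
      values = values, state = state, log = log
    ),
    class = "DescriptorTable"
  )
}

#' @export
print.DescriptorTable <- function(x, ...) {
  cat(sprintf(
    "DescriptorTable: %d compounds x %d features [state: %s, %.1f%% missing]\n",
    nrow(x$values), ncol(x$values), x$state,
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.DescriptorTable <- function(x) dim(x$values)

#' The full 2D descriptor catalogue
#'
#' Names of all 1613 two-dimensional descriptors, grouped into families
#' (autocorrelation, matrix-spectral, connectivity, counts, E-state, ...).
#'
#' @param by_family if TRUE, return a named list of name vectors per family
#' @return character vector of 1613 descriptor names (or a list)
#' @export
descriptor_catalogue <- function(by_family = FALSE) {
  fams <- .desc_families()
  if (by_family) return(lapply(fams, `[[`, "names"))
  unlist(lapply(fams, `[[`, "names"), use.names = FALSE)
}

# Molecule-level aux data shared across families (OpenBabel properties,
# SMARTS ring counts, path/cycle enumeration, ring membership).
.compute_aux <- function(ctx, props_row, rings_row) {
  list(
    props = props_row,
    rings = rings_row,
    inring = ring_atoms(ctx),
    paths = path_stats(ctx, 10L),
    cycles = cycle_stats(ctx, 7L)
  )
}

#' Compute the 2D descriptor table for curated compounds
#'
#' One row per compound over the full descriptor catalogue. Descriptors that
#' cannot be computed for a molecule (missing atomic parameters, disconnected
#' or single-atom graphs, absent substructures with undefined statistics) are
#' recorded as missing values, never as zero.
#'
#' @param records standardized molecule records (or a character vector of
#'   standardized SMILES)
#' @return a `DescriptorTable` in state `raw`
#' @export
compute_descriptors <- function(records) {
  if (is.character(records)) {
    records <- data.frame(
      id = paste0("cmpd", seq_along(records)),
      canonical_smiles = records, stringsAsFactors = FALSE
    )
  }
  smiles <- records$canonical_smiles
  tk_assert(length(smiles) > 0, "no compounds")
  bad <- is.na(smiles) | !nzchar(smiles)
  if (any(bad)) {
    tk_stop(
      "records without canonical SMILES (run standardize_molecules first): %s",
      paste(records$id[bad], collapse = ", ")
    )
  }
  ctxs <- mol_graphs(smiles)
  fail <- vapply(ctxs, is.null, TRUE)
  if (any(fail)) {
    tk_stop("unparseable structures: %s", paste(records$id[fail], collapse = ", "))
  }

  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
  props <- do.call(rbind, lapply(mols, function(m) {
    tryCatch(ChemmineOB::prop_OB(m), error = function(e) NULL)
  }))
  ring_pats <- paste0("[r", 3:12, "]")
  rings <- vapply(
    ring_pats,
    function(p) as.numeric(ChemmineOB::smartsSearch_OB(mols, p)),
    numeric(length(smiles))
  )
  if (length(smiles) == 1) rings <- matrix(rings, nrow = 1)

  fams <- .desc_families()
  catalogue <- descriptor_catalogue()
  values <- matrix(NA_real_, length(smiles), length(catalogue),
    dimnames = list(records$id, catalogue)
  )
  for (k in seq_along(smiles)) {
    ctx <- ctxs[[k]]
    aux <- .compute_aux(
      ctx,
      if (!is.null(props) && k <= nrow(props)) props[k, , drop = FALSE] else NULL,
      rings[k, ]
    )
    row <- unlist(lapply(fams, function(f) f$compute(ctx, aux)), use.names = FALSE)
    values[k, ] <- row
  }
  nexp <- 1613L
  log <- sprintf(
    "computed %d descriptors for %d compounds%s",
    ncol(values), nrow(values),
    if (ncol(values) != nexp) {
      sprintf(" (WARNING: catalogue width %d differs from expected %d)", ncol(values), nexp)
    } else {
      ""
    }
  )
  descriptor_table(values, state = "raw", log = log)
}

#' Write / read a descriptor table as CSV
#'
#' Header row = feature names, first column = compound id, empty field =
#' missing value.
#' @param table a DescriptorTable
#' @param path file path
#' @export
write_descriptors <- function(table, path) {
  df <- data.frame(id = table$ids, table$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_descriptors
#' @param state state to stamp on the table read from `path`
#' @export
read_descriptors <- function(path, state = "raw") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  descriptor_table(m, state = state)
}
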