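# Compound ingestion, standardization, deduplication and partitioning.
#
# Structure normalization follows the ChEMBL-style curation protocol: parse
# check, functional-group/charge normalization (neutralize), parent-molecule
# extraction (largest fragment), canonical SMILES as the identity key.

TASTE_CLASSES <- c("bitter", "sweet", "other", "umami")

#' Construct molecule records
#'
#' @param input character vector of molecular notations (SMILES, InChI,
#'   peptide FASTA, SMARTS) one compound per element
#' @param id optional compound identifiers (default `cmpd1..n`)
#' @param label optional taste labels (`bitter`, `sweet`, `umami`, `other`)
#' @param format optional notation override; auto-detected when `NA`
#' @return a `data.frame` of molecule records with columns `id`, `input_text`,
#'   `input_format`, `canonical_smiles`, `label`, `issues`
#' @export
molecule_records <- function(input, id = NULL, label = NULL, format = NULL) {
  n <- length(input)
  tk_assert(n > 0, "no input compounds")
  id <- id %||% paste0("cmpd", seq_len(n))
  label <- label %||% rep(NA_character_, n)
  label <- as.character(label)
  known <- is.na(label) | label %in% TASTE_CLASSES
  tk_assert(all(known), "unknown taste label(s): %s",
    paste(unique(label[!known]), collapse = ", "))
  fmt <- format %||% rep(NA_character_, n)
  data.frame(
    id = as.character(id), input_text = trimws(as.character(input)),
    input_format = fmt, canonical_smiles = NA_character_,
    label = label, issues = "", stringsAsFactors = FALSE
  )
}

# Batch canonical SMILES via obabel; NA where unparseable.
canonicalize_smiles <- function(smiles, extra_args = character(0)) {
  if (length(smiles) == 0) return(character(0))
  ok <- !is.na(smiles) & nzchar(smiles)
  out <- rep(NA_character_, length(smiles))
  if (any(ok)) {
    tags <- paste0("TKC", which(ok))
    lines <- run_obabel(
      paste(smiles[ok], tags),
      c("-ismi", "-ocan", "-e", extra_args)
    )
    parts <- strsplit(trimws(lines), "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2 && startsWith(p[2], "TKC")) {
        out[as.integer(sub("TKC", "", p[2]))] <- p[1]
      }
    }
  }
  out
}

.AA_ALPHABET <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Detect the notation of a molecular input string
#'
#' Deterministic detection order: InChI prefix, then parseable SMILES, then
#' amino-acid-alphabet-only (peptide FASTA), then SMARTS-like syntax, then a
#' free-text compound name.
#'
#' @param text character vector of input strings
#' @return character vector in
#'   `c("smiles","inchi","smarts","fasta","name")`
#' @export
detect_format <- function(text) {
  tk_assert(is.character(text) && length(text) >= 1, "text must be character")
  text <- trimws(text)
  tk_assert(all(nzchar(text)), "empty input string")
  out <- rep(NA_character_, length(text))
  out[startsWith(text, "InChI=")] <- "inchi"
  todo <- is.na(out)
  if (any(todo)) {
    can <- canonicalize_smiles(text[todo])
    res <- ifelse(!is.na(can), "smiles",
      ifelse(grepl(.AA_ALPHABET, text[todo]), "fasta",
        ifelse(grepl("[][()=#*~@$;,!&+]", text[todo]), "smarts", "name")
      )
    )
    out[todo] <- res
  }
  out
}

inchi_to_smiles <- function(inchi) {
  out <- rep(NA_character_, length(inchi))
  for (k in seq_along(inchi)) {
    r <- run_obabel(inchi[k], c("-iinchi", "-ocan", "-e"))
    r <- trimws(r)
    r <- r[nzchar(r)]
    if (length(r) >= 1) out[k] <- strsplit(r[1], "[ \t]+")[[1]][1]
  }
  out
}

.add_issue <- function(issues, flag) {
  ifelse(nzchar(issues), paste(issues, flag, sep = ";"), flag)
}

#' Standardize molecule records
#'
#' Resolves each record to a canonical standardized parent structure:
#' peptides are condensed to SMILES, InChI is converted, then every structure
#' passes a parse check, charge neutralization and largest-fragment (salt /
#' solvate) stripping. Findings are appended to `issues`; structures that fail
#' to parse receive a `fatal:unparseable` flag and a missing
#' `canonical_smiles`.
#'
#' @param records molecule records from [molecule_records()]
#' @param resolver optional function(name) -> SMILES used for `name` inputs;
#'   by default name resolution is disabled (no network dependency)
#' @return records with `canonical_smiles`, `input_format` and `issues` filled
#' @export
standardize_molecules <- function(records, resolver = NULL) {
  tk_assert(nrow(records) > 0, "no records")
  fmt <- records$input_format
  if (anyNA(fmt)) {
    fmt[is.na(fmt)] <- detect_format(records$input_text[is.na(fmt)])
  }
  records$input_format <- fmt

  smi <- rep(NA_character_, nrow(records))
  smi[fmt %in% c("smiles", "smarts")] <- records$input_text[fmt %in% c("smiles", "smarts")]
  for (k in which(fmt == "fasta")) {
    smi[k] <- tryCatch(peptide_to_smiles(records$input_text[k]), error = function(e) NA)
    if (is.na(smi[k])) records$issues[k] <- .add_issue(records$issues[k], "fatal:bad_peptide")
  }
  if (any(fmt == "inchi")) {
    smi[fmt == "inchi"] <- inchi_to_smiles(records$input_text[fmt == "inchi"])
  }
  for (k in which(fmt == "name")) {
    if (is.null(resolver)) {
      records$issues[k] <- .add_issue(records$issues[k], "fatal:name_resolution_disabled")
    } else {
      smi[k] <- resolver(records$input_text[k])
    }
  }

  raw_can <- canonicalize_smiles(smi)
  parent_can <- canonicalize_smiles(smi, c("-r", "--neutralize"))
  for (k in seq_len(nrow(records))) {
    if (is.na(smi[k]) || is.na(raw_can[k]) || is.na(parent_can[k])) {
      if (!grepl("fatal:", records$issues[k])) {
        records$issues[k] <- .add_issue(records$issues[k], "fatal:unparseable")
      }
      next
    }
    if (grepl("\\.", raw_can[k])) {
      records$issues[k] <- .add_issue(records$issues[k], "fragment_stripped")
    }
    stripped_can <- canonicalize_smiles(raw_can[k], "-r")
    if (!is.na(stripped_can) && !identical(stripped_can, parent_can[k])) {
      records$issues[k] <- .add_issue(records$issues[k], "neutralized")
    }
    records$canonical_smiles[k] <- parent_can[k]
  }
  records
}

has_fatal_issue <- function(records) grepl("fatal:", records$issues)

#' Deduplicate standardized records by canonical structure
#'
#' Keeps at most one record per canonical SMILES. Structures that appear with
#' conflicting taste labels are removed entirely (a structure with two labels
#' poisons a single-label classifier); fatal records are dropped.
#'
#' @param records standardized molecule records
#' @return deduplicated records; removed rows are attached as
#'   `attr(x, "removed")`
#' @export
deduplicate_molecules <- function(records) {
  ok <- !has_fatal_issue(records) & !is.na(records$canonical_smiles)
  removed <- records[!ok, , drop = FALSE]
  recs <- records[ok, , drop = FALSE]
  keep <- logical(nrow(recs))
  for (smi in unique(recs$canonical_smiles)) {
    idx <- which(recs$canonical_smiles == smi)
    labs <- unique(recs$label[idx])
    labs <- labs[!is.na(labs)]
    if (length(labs) > 1) {
      recs$issues[idx] <- .add_issue(recs$issues[idx], "cross_label_conflict")
    } else {
      keep[idx[1]] <- TRUE
    }
  }
  removed <- rbind(removed, recs[!keep, , drop = FALSE])
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Split curated records into train and test sets by per-class quota
#'
#' Draws the requested number of compounds per class uniformly at random
#' without replacement; everything else forms the external test set.
#'
#' @param records deduplicated, labelled molecule records
#' @param quota named integer vector, class -> training count
#' @param seed integer RNG seed
#' @return list with `train`, `test` (record data.frames) and
#'   `per_class_train_quota`
#' @export
make_split <- function(records, quota, seed = 1L) {
  tk_assert(all(!is.na(records$label)), "all records must be labelled")
  counts <- table(records$label)
  for (cl in names(quota)) {
    n_cl <- if (cl %in% names(counts)) counts[[cl]] else 0L
    if (quota[[cl]] > n_cl) {
      tk_stop("quota %d exceeds class size %d for class '%s'", quota[[cl]], n_cl, cl)
    }
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in names(quota)) {
    idx <- which(records$label == cl)
    if (quota[[cl]] > 0) {
      train_idx <- c(train_idx, sort(sample(idx, quota[[cl]])))
    }
  }
  train <- records[train_idx, , drop = FALSE]
  test <- records[setdiff(seq_len(nrow(records)), train_idx), , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, per_class_train_quota = quota)
}

#' Read compounds from a text or CSV file
#'
#' CSV files need columns `id,input` and optionally `label`; plain text files
#' are one compound notation per line.
#' @param path file path
#' @return molecule records
#' @export
read_compounds <- function(path) {
  tk_assert(file.exists(path), "input file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (grepl(",", first) && grepl("(^|,)input(,|$)", first)) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    molecule_records(df$input,
      id = if ("id" %in% names(df)) df$id else NULL,
      label = if ("label" %in% names(df)) df$label else NULL
    )
  } else {
    lines <- trimws(readLines(path))
    molecule_records(lines[nzchar(lines)])
  }
}

#' Write curated records to CSV
#' @param records molecule records
#' @param path output path
#' @export
write_curated <- function(records, path) {
  write.csv(
    records[, c("id", "canonical_smiles", "label", "issues")],
    path,
    row.names = FALSE, na = ""
  )
  invisible(path)
}
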