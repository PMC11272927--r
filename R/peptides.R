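# Linear peptide assembly: one-letter sequence -> SMILES with free N-terminal
# amine, C-terminal carboxylic acid and L-stereocentres at every alpha carbon
# (glycine achiral; proline handled as the cyclic imino acid).

.SIDE_CHAINS <- c(
  A = "C",
  R = "CCCNC(=N)N",
  N = "CC(N)=O",
  D = "CC(=O)O",
  C = "CS",
  E = "CCC(=O)O",
  Q = "CCC(N)=O",
  H = "Cc1c[nH]cn1",
  I = "[C@@H](C)CC",
  K = "CCCCN",
  L = "CC(C)C",
  M = "CCSC",
  F = "Cc1ccccc1",
  S = "CO",
  T = "[C@H](O)C",
  V = "C(C)C",
  W = "Cc1c[nH]c2ccccc12",
  Y = "Cc1ccc(O)cc1"
)

.residue_unit <- function(aa) {
  if (aa == "G") return("NCC(=O)")
  if (aa == "P") return("N1CCC[C@H]1C(=O)")
  paste0("N[C@@H](", .SIDE_CHAINS[[aa]], ")C(=O)")
}

#' Convert a peptide sequence to SMILES
#'
#' Builds the linear peptide by amide condensation of the 20 canonical
#' L-amino acids, leaving a free N-terminal amine and C-terminal acid.
#'
#' @param sequence one-letter amino-acid string (canonical 20 letters)
#' @return a SMILES string (not canonicalized; feed through [standardize_molecules()])
#' @examples
#' peptide_to_smiles("G")   # glycine
#' peptide_to_smiles("GG")  # glycylglycine
#' @export
peptide_to_smiles <- function(sequence) {
  tk_assert(is.character(sequence) && length(sequence) == 1, "sequence must be a single string")
  sequence <- toupper(trimws(sequence))
  tk_assert(nchar(sequence) > 0, "empty peptide sequence")
  aas <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aas, c(names(.SIDE_CHAINS), "G", "P"))
  if (length(bad)) {
    tk_stop("invalid residue(s) in peptide sequence: %s", paste(unique(bad), collapse = ", "))
  }
  paste0(paste(vapply(aas, .residue_unit, ""), collapse = ""), "O")
}
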