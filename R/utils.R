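#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate cor kruskal.test median p.adjust prcomp
#'   quantile rnorm runif rlnorm sd setNames shapiro.test wilcox.test var
#'   predict rbinom
#' @importFrom utils read.csv write.csv head tail packageVersion
NULL

the_classes <- c("bitter", "sweet", "other", "umami")

`%||%` <- function(a, b) if (is.null(a)) b else a

tk_stop <- function(...) stop(sprintf(...), call. = FALSE)

tk_assert <- function(cond, ...) if (!isTRUE(cond)) tk_stop(...)

#' Run obabel with input text on stdin
#'
#' Thin wrapper around the OpenBabel command line used for format conversion
#' and standardization. Errors if the binary is absent.
#' @param input character vector of input lines
#' @param args character vector of obabel arguments
#' @return character vector of stdout lines
#' @keywords internal
run_obabel <- function(input, args) {
  if (Sys.which("obabel") == "") {
    tk_stop("obabel not found on PATH; OpenBabel is required")
  }
  out <- suppressWarnings(system2("obabel", args,
    input = input,
    stdout = TRUE, stderr = FALSE
  ))
  as.character(out)
}

# Deterministic sub-seed derivation: keeps derived seeds positive 31-bit ints.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %% 2147483647)
}
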