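## Amino-acid alphabet constants shared across modules.

#' The 20 standard amino acids (one-letter codes)
#'
#' Alphabet used throughout the package; any other letter is rejected by the
#' catalog parser and the matrix readers.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## three-letter -> one-letter lookup (case-insensitive after normalization)
AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V")

#' Default amino-acid polarity scheme
#'
#' Maps each standard amino acid to one of four polarity classes:
#' `hydrophobic`, `polar` (uncharged), `charged_negative`, `charged_positive`.
#' Glycine and proline are grouped with the hydrophobic class for the purpose
#' of detecting polarity *transitions*; the scheme is a replaceable default,
#' not a physical constant.
#'
#' @format Named character vector (names = one-letter amino acids).
#' @export
POLARITY_DEFAULT <- c(
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic", F = "hydrophobic", W = "hydrophobic", C = "hydrophobic",
  P = "hydrophobic", G = "hydrophobic",
  S = "polar", T = "polar", N = "polar", Q = "polar", Y = "polar", H = "polar",
  D = "charged_negative", E = "charged_negative",
  K = "charged_positive", R = "charged_positive")

aa_check <- function(aa, what = "amino acid") {
  bad <- !(aa %in% AA_STANDARD)
  if (any(bad)) {
    abort(sprintf("non-standard %s: %s", what,
                  paste(unique(aa[bad]), collapse = ", ")),
          class = "mutriage_error_nonstandard_aa")
  }
  invisible(aa)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
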