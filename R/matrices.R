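## substitution_features: substitution-matrix penalties and polarity
## transitions.

#' Read a square substitution matrix in NCBI-style text format
#'
#' Whitespace-separated square table with one header row of one-letter
#' amino acids and one labelled row per amino acid; `#` lines are comments.
#' The matrix must cover all 20 standard residues and be symmetric.
#'
#' @param path Matrix file.
#' @param name Matrix name; defaults to the file base name.
#' @return A `substitution_matrix`: 20 x 20 numeric matrix with `name`
#'   attribute.
#' @export
read_substitution_matrix <- function(path, name = NULL) {
  m <- as.matrix(utils::read.table(path, header = TRUE, comment.char = "#",
                                   check.names = FALSE, row.names = 1))
  if (!all(AA_STANDARD %in% rownames(m)) || !all(AA_STANDARD %in% colnames(m))) {
    abort("substitution matrix must cover all 20 standard amino acids",
          class = "mutriage_error_matrix")
  }
  m <- m[AA_STANDARD, AA_STANDARD]
  if (!isSymmetric(unname(m))) {
    abort("substitution matrix is not symmetric",
          class = "mutriage_error_matrix")
  }
  structure(m, name = name %||% sub("\\.[^.]*$", "", basename(path)),
            class = c("substitution_matrix", "matrix", "array"))
}

#' Bundled substitution matrices
#'
#' `blosum62_matrix()` returns the canonical BLOSUM62 table.
#' `cbsm60_synthetic_matrix()` returns the bundled *synthetic stand-in* for a
#' conformation-specific matrix (symmetric scores derived from hydropathy and
#' side-chain volume distances) used for interface and property tests; it
#' does not reproduce published CBSM60 values, and the talin-1 reference
#' reproduction uses the normalized-score fixture table instead.
#'
#' @return A `substitution_matrix`.
#' @export
blosum62_matrix <- function() {
  read_substitution_matrix(
    system.file("extdata", "matrices", "blosum62.txt", package = "mutriage"),
    name = "BLOSUM62")
}

#' @rdname blosum62_matrix
#' @export
cbsm60_synthetic_matrix <- function() {
  read_substitution_matrix(
    system.file("extdata", "matrices", "cbsm60_synthetic.txt",
                package = "mutriage"),
    name = "CBSM60")
}

#' Raw substitution-matrix score
#'
#' Exact table lookup of `score(wt, mut)`.
#'
#' @param wt,mut One-letter amino acids (vectors recycle).
#' @param matrix A `substitution_matrix`.
#' @export
matrix_score <- function(wt, mut, matrix) {
  aa_check(wt); aa_check(mut)
  unname(matrix[cbind(wt, mut)])
}

#' Normalized substitution penalty
#'
#' Two schemes coexist. `row_range` is the computable default:
#' `(score(wt, wt) - score(wt, mut)) / (score(wt, wt) - min(score(wt, .)))`,
#' clamped to \[0, 1\] — zero at identity, one for the most penalized
#' substitution in the wild-type row. `fixture` looks the value up verbatim
#' in a supplied normalized-score table (tibble with columns `wt`, `mut`,
#' `matrix`, `value`; values may be negative), carrying externally computed
#' normalizations that no simple per-substitution rule reproduces.
#'
#' @param wt,mut One-letter amino acids (vectors recycle).
#' @param matrix A `substitution_matrix`.
#' @param scheme `"row_range"` or `"fixture"`.
#' @param fixture Normalized-score table, required for the fixture scheme
#'   (see [load_norm_fixture()]).
#' @return Numeric vector of normalized penalties.
#' @export
normalize_substitution <- function(wt, mut, matrix,
                                   scheme = c("row_range", "fixture"),
                                   fixture = NULL) {
  scheme <- match.arg(scheme)
  aa_check(wt); aa_check(mut)
  if (scheme == "row_range") {
    self <- matrix[cbind(wt, wt)]
    raw <- matrix[cbind(wt, mut)]
    rowmin <- apply(matrix[, AA_STANDARD, drop = FALSE], 1, min)[wt]
    out <- (self - raw) / (self - rowmin)
    return(unname(clamp(out, 0, 1)))
  }
  if (is.null(fixture)) {
    abort("fixture scheme requires a normalized-score table",
          class = "mutriage_error_matrix")
  }
  mname <- attr(matrix, "name")
  key <- paste(wt, mut, mname)
  fkey <- paste(fixture$wt, fixture$mut, fixture$matrix)
  idx <- match(key, fkey)
  if (anyNA(idx)) {
    abort(sprintf("no fixture normalization for %s under matrix %s",
                  paste(unique(paste0(wt, ">", mut)[is.na(idx)]),
                        collapse = ", "), mname),
          class = "mutriage_error_missing_evidence")
  }
  fixture$value[idx]
}

#' Load a normalized-score fixture table
#'
#' TSV with columns `wt`, `mut`, `matrix`, `value`; consistent duplicate
#' rows collapse, conflicting duplicates are an error.
#'
#' @param path TSV file.
#' @export
load_norm_fixture <- function(path) {
  fx <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("wt", "mut", "matrix", "value")
  if (!all(need %in% names(fx))) {
    abort("normalized-score fixture needs columns wt, mut, matrix, value",
          class = "mutriage_error_matrix")
  }
  fx <- distinct(fx, .data$wt, .data$mut, .data$matrix, .data$value)
  if (anyDuplicated(paste(fx$wt, fx$mut, fx$matrix))) {
    abort("conflicting duplicate entries in normalized-score fixture",
          class = "mutriage_error_matrix")
  }
  fx
}

#' Polarity-transition class of a substitution
#'
#' Classifies the ordered pair of polarity classes of the wild-type and
#' mutant residues: `none` (same class), `hydrophobic->polar`,
#' `hydrophobic->charged`, `polar->hydrophobic`, `charge_change`
#' (positive/negative swap) or `other`.
#'
#' @param wt,mut One-letter amino acids (vectors recycle).
#' @param scheme Named vector mapping amino acids to polarity classes
#'   (default [POLARITY_DEFAULT]).
#' @return Character vector of transition classes.
#' @export
polarity_transition <- function(wt, mut, scheme = POLARITY_DEFAULT) {
  aa_check(wt); aa_check(mut)
  if (!all(AA_STANDARD %in% names(scheme))) {
    abort("polarity scheme must assign all 20 standard amino acids",
          class = "mutriage_error_matrix")
  }
  a <- scheme[wt]
  b <- scheme[mut]
  charged <- c("charged_positive", "charged_negative")
  out <- rep("other", length(a))
  out[a == b] <- "none"
  out[a == "hydrophobic" & b == "polar"] <- "hydrophobic->polar"
  out[a == "hydrophobic" & b %in% charged] <- "hydrophobic->charged"
  out[a == "polar" & b == "hydrophobic"] <- "polar->hydrophobic"
  out[(a == "charged_positive" & b == "charged_negative") |
      (a == "charged_negative" & b == "charged_positive")] <- "charge_change"
  unname(out)
}
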