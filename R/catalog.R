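## catalog_io: parse, validate and serialize COSMIC-style mutation catalogs.

#' Parse a protein-level substitution token
#'
#' Accepts `"L2509P"`, `"p.L2509P"` and three-letter dialect
#' (`"p.Leu2509Pro"`); parsing is case-normalizing and the canonical id never
#' carries the `"p."` prefix. Coordinates are 1-based protein residue indices.
#'
#' @param token Character vector of substitution tokens.
#' @return A tibble with columns `wt_aa`, `position`, `mut_aa`, `id` (one row
#'   per token, input order preserved).
#' @examples
#' parse_substitution(c("L2509P", "p.I392N", "p.Leu1539Pro"))
#' @export
parse_substitution <- function(token) {
  stopifnot(is.character(token), length(token) > 0)
  stripped <- sub("^[pP]\\.", "", trimws(token))
  re <- "^([A-Za-z]{3}|[A-Za-z])([0-9]+)([A-Za-z]{3}|[A-Za-z])$"
  ok <- grepl(re, stripped)
  if (any(!ok)) {
    abort(sprintf("malformed substitution token(s): %s",
                  paste(unique(token[!ok]), collapse = ", ")),
          class = c("mutriage_error_malformed", "mutriage_error_parse"))
  }
  wt  <- aa_normalize(sub(re, "\\1", stripped), token)
  mut <- aa_normalize(sub(re, "\\3", stripped), token)
  pos <- as.integer(sub(re, "\\2", stripped))
  if (any(pos < 1L)) {
    abort("residue positions must be >= 1",
          class = c("mutriage_error_malformed", "mutriage_error_parse"))
  }
  syn <- wt == mut
  if (any(syn)) {
    abort(sprintf("synonymous substitution(s) rejected: %s",
                  paste(unique(token[syn]), collapse = ", ")),
          class = c("mutriage_error_synonymous", "mutriage_error_parse"))
  }
  tibble(wt_aa = wt, position = pos, mut_aa = mut,
         id = format_substitution(wt, pos, mut))
}

## normalize a matched 1- or 3-letter code to upper-case one-letter form
aa_normalize <- function(code, token) {
  three <- nchar(code) == 3L
  out <- toupper(code)
  if (any(three)) {
    key <- paste0(substr(out[three], 1, 1), tolower(substr(out[three], 2, 3)))
    hit <- AA_THREE_TO_ONE[key]
    if (anyNA(hit)) {
      abort(sprintf("non-standard amino acid in token(s): %s",
                    paste(unique(token[three][is.na(hit)]), collapse = ", ")),
            class = c("mutriage_error_nonstandard_aa", "mutriage_error_parse"))
    }
    out[three] <- hit
  }
  bad <- !(out %in% AA_STANDARD)
  if (any(bad)) {
    abort(sprintf("non-standard amino acid in token(s): %s",
                  paste(unique(token[bad]), collapse = ", ")),
          class = c("mutriage_error_nonstandard_aa", "mutriage_error_parse"))
  }
  out
}

#' Format a substitution id
#'
#' Inverse of [parse_substitution()]: `format_substitution("L", 2509, "P")`
#' is `"L2509P"`.
#'
#' @param wt,mut One-letter amino acids.
#' @param position 1-based residue index.
#' @export
format_substitution <- function(wt, position, mut) {
  paste0(wt, as.integer(position), mut)
}

## classify a raw catalog token without throwing: missense / synonymous /
## nonsense / frameshift / other
classify_token <- function(token) {
  stripped <- sub("^[pP]\\.", "", trimws(token))
  out <- rep("other", length(token))
  out[grepl("fs", stripped, ignore.case = TRUE)] <- "frameshift"
  non <- grepl("^([A-Za-z]{3}|[A-Za-z])[0-9]+(\\*|[Tt]er)$", stripped)
  out[non] <- "nonsense"
  re <- "^([A-Za-z]{3}|[A-Za-z])([0-9]+)([A-Za-z]{3}|[A-Za-z])$"
  cand <- out == "other" & grepl(re, stripped)
  if (any(cand)) {
    cls <- vapply(token[cand], function(tk) {
      tryCatch({ parse_substitution(tk); "missense" },
               mutriage_error_synonymous = function(e) "synonymous",
               mutriage_error_parse = function(e) "other")
    }, character(1))
    out[cand] <- cls
  }
  out
}

#' Load a reference protein sequence from FASTA
#'
#' @param path FASTA file with a single amino-acid record.
#' @return A `reference_sequence` object (list with `name`, `residues`,
#'   `length`); residues use 1-based indexing.
#' @export
load_reference <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1L) {
    abort("reference FASTA must contain exactly one record",
          class = "mutriage_error_reference")
  }
  res <- strsplit(as.character(set[[1]]), "")[[1]]
  aa_check(res, "reference residue")
  structure(list(name = names(set), residues = res, length = length(res)),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat("<reference_sequence>", x$name, "\n  length:", x$length, "residues\n")
  invisible(x)
}

#' Load a COSMIC-style mutation catalog
#'
#' Reads a delimited text file, retains missense rows, and drops (with a
#' tallied report) nonsense, frameshift, synonymous and unparseable rows.
#' Duplicate ids are merged by summing recurrence; metadata of merged rows is
#' joined with `"/"`. Input row order is preserved.
#'
#' @param path Delimited text file.
#' @param columns Named list mapping the fields `mutation` (mandatory),
#'   `recurrence`, `tissue`, `histology` to column names in the file; set an
#'   entry to `NULL` to fill a default (recurrence 1, metadata `NA`).
#' @param delim Field delimiter; guessed from the extension when `NULL`
#'   (`.csv` comma, otherwise tab).
#' @return Tibble with columns `wt_aa`, `position`, `mut_aa`, `id`,
#'   `recurrence`, `tissue`, `histology`; the drop tally (named integer,
#'   classes x counts) is attached as attribute `"dropped"`.
#' @export
load_catalog <- function(path,
                         columns = list(mutation = "mutation",
                                        recurrence = "recurrence",
                                        tissue = "primary_tissue",
                                        histology = "histology"),
                         delim = NULL) {
  if (!file.exists(path)) {
    abort(paste("catalog file not found:", path), class = "mutriage_error_io")
  }
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  if (is.null(columns$mutation)) {
    abort("a mutation column must be configured", class = "mutriage_error_io")
  }
  need <- unlist(columns)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("catalog is missing configured column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "mutriage_error_io")
  }
  token <- as.character(raw[[columns$mutation]])
  if (length(token) == 0L) {
    out <- tibble(wt_aa = character(), position = integer(),
                  mut_aa = character(), id = character(),
                  recurrence = integer(), tissue = character(),
                  histology = character())
    attr(out, "dropped") <- integer(0)
    return(out)
  }
  cls <- classify_token(token)
  keep <- cls == "missense"
  dropped <- table(cls[!keep])
  dropped <- setNames(as.integer(dropped), names(dropped))
  if (sum(dropped) > 0) {
    message(sprintf("load_catalog: dropped %d non-missense row(s) [%s]",
                    sum(dropped),
                    paste(names(dropped), dropped, sep = "=", collapse = ", ")))
  }
  parsed <- parse_substitution(token[keep])
  grab <- function(field, default) {
    if (is.null(columns[[field]])) rep(default, sum(keep))
    else raw[[columns[[field]]]][keep]
  }
  rec <- grab("recurrence", 1L)
  rec <- as.integer(rec)
  if (anyNA(rec) || any(rec < 0L)) {
    abort("recurrence must be a non-negative integer",
          class = "mutriage_error_io")
  }
  out <- parsed
  out$recurrence <- rec
  out$tissue <- as.character(grab("tissue", NA_character_))
  out$histology <- as.character(grab("histology", NA_character_))
  out <- merge_duplicate_ids(out)
  attr(out, "dropped") <- dropped
  out
}

## merge rows sharing an id: recurrence summed, metadata joined, first
## occurrence keeps its catalog position
merge_duplicate_ids <- function(catalog) {
  if (!anyDuplicated(catalog$id)) return(catalog)
  catalog$.ord <- seq_len(nrow(catalog))
  join_meta <- function(x) paste(unique(x[!is.na(x)]), collapse = "/")
  out <- catalog |>
    group_by(.data$id) |>
    summarise(wt_aa = .data$wt_aa[1], position = .data$position[1],
              mut_aa = .data$mut_aa[1],
              recurrence = sum(.data$recurrence),
              tissue = join_meta(.data$tissue),
              histology = join_meta(.data$histology),
              .ord = min(.data$.ord), .groups = "drop") |>
    arrange(.data$.ord) |>
    select("wt_aa", "position", "mut_aa", "id",
           "recurrence", "tissue", "histology")
  out$tissue[out$tissue == ""] <- NA_character_
  out$histology[out$histology == ""] <- NA_character_
  out
}

#' Validate a catalog against a reference sequence
#'
#' Checks that each record's position lies inside the reference and that the
#' wild-type letter matches the reference residue. Failing records are
#' collected into a validation report (attribute `"report"`: tibble with
#' `id`, `failure`, `detail`), never silently dropped.
#'
#' @param catalog Tibble from [load_catalog()].
#' @param ref A `reference_sequence` from [load_reference()].
#' @return The surviving records (input order preserved) with the report
#'   attached as attribute `"report"`.
#' @export
validate_catalog <- function(catalog, ref) {
  stopifnot(inherits(ref, "reference_sequence"))
  n <- nrow(catalog)
  failure <- rep(NA_character_, n)
  detail <- rep(NA_character_, n)
  oob <- catalog$position > ref$length
  failure[oob] <- "out_of_range"
  detail[oob] <- sprintf("position %d exceeds reference length %d",
                         catalog$position[oob], ref$length)
  inb <- !oob
  refaa <- rep(NA_character_, n)
  refaa[inb] <- ref$residues[catalog$position[inb]]
  mm <- inb & refaa != catalog$wt_aa
  failure[mm] <- "wt_mismatch"
  detail[mm] <- sprintf("catalog says %s but reference residue %d is %s",
                        catalog$wt_aa[mm], catalog$position[mm], refaa[mm])
  report <- tibble(id = catalog$id, failure = failure, detail = detail) |>
    filter(!is.na(.data$failure))
  out <- catalog[is.na(failure), , drop = FALSE]
  attr(out, "report") <- report
  attr(out, "dropped") <- attr(catalog, "dropped")
  out
}

#' Write a validated catalog (or its validation report) as TSV
#'
#' @param catalog Catalog tibble.
#' @param path Output file.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(as_tibble(catalog), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
write_validation_report <- function(catalog, path) {
  report <- attr(catalog, "report")
  if (is.null(report)) report <- tibble(id = character(),
                                        failure = character(),
                                        detail = character())
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
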