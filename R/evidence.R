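## evidence_ingest: external predictor evidence (pathogenicity probability,
## per-residue conservation) read from delimited files, never from live
## services.

#' Load per-mutation pathogenicity probabilities
#'
#' Delimited file with columns `id` (canonical substitution id) and
#' `probability` in \[0, 1\]. Identical duplicate rows collapse; duplicate
#' ids with conflicting probabilities are an error.
#'
#' @param path TSV/CSV file (`#` lines are comments).
#' @return Tibble with `id`, `probability`.
#' @export
load_pathogenicity <- function(path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  ev <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  if (!all(c("id", "probability") %in% names(ev))) {
    abort("pathogenicity file needs columns id, probability",
          class = "mutriage_error_evidence")
  }
  ev <- distinct(ev, .data$id, .data$probability)
  if (anyDuplicated(ev$id)) {
    dup <- unique(ev$id[duplicated(ev$id)])
    abort(sprintf("conflicting probabilities for id(s): %s",
                  paste(dup, collapse = ", ")),
          class = "mutriage_error_evidence")
  }
  if (any(ev$probability < 0 | ev$probability > 1)) {
    abort("pathogenicity probabilities must lie in [0, 1]",
          class = "mutriage_error_evidence")
  }
  select(ev, "id", "probability")
}

#' Load a per-residue conservation profile
#'
#' Reads a delimited table keyed by `position` with one value column:
#' `grade` (integer 1-9, discrete conservation grades), `score`
#' (continuous), or `value` (already-normalized passthrough). The mode can
#' be forced or inferred from which column is present
#' (`value` > `grade` > `score` precedence under `"auto"`).
#'
#' @param path TSV file (`#` comment lines tolerated, as in grade exports).
#' @param mode `"auto"`, `"grade"`, `"continuous"` or `"fixture"`.
#' @return A `conservation_profile` (tibble of `position`, `raw` plus a
#'   `mode` attribute).
#' @export
load_conservation <- function(path,
                              mode = c("auto", "grade", "continuous",
                                       "fixture")) {
  mode <- match.arg(mode)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!"position" %in% names(tab)) {
    abort("conservation file needs a position column",
          class = "mutriage_error_evidence")
  }
  col <- switch(mode,
    grade = "grade", continuous = "score", fixture = "value",
    auto = intersect(c("value", "grade", "score"), names(tab))[1])
  if (is.na(col) || !col %in% names(tab)) {
    abort("conservation file lacks a usable value column (value/grade/score)",
          class = "mutriage_error_evidence")
  }
  if (mode == "auto") {
    mode <- c(value = "fixture", grade = "grade", score = "continuous")[[col]]
  }
  out <- tibble(position = as.integer(tab$position),
                raw = as.numeric(tab[[col]]))
  if (anyDuplicated(out$position)) {
    abort("duplicate positions in conservation profile",
          class = "mutriage_error_evidence")
  }
  if (mode == "grade" && any(out$raw < 1 | out$raw > 9)) {
    abort("conservation grades must lie in 1..9",
          class = "mutriage_error_evidence")
  }
  structure(out, mode = mode, class = c("conservation_profile", class(out)))
}

#' Normalized conservation at catalog positions
#'
#' Grade mode maps grade g to `(g - 1) / 8`; continuous mode min-max scales
#' over the whole profile; fixture mode passes values through verbatim
#' (range-checked to \[-1, 1\], with a warning if outside \[0, 1\]).
#' Positions absent from the profile return `NA` — an explicit
#' missing-evidence marker, never a silent zero.
#'
#' @param profile A `conservation_profile`.
#' @param position Integer vector of residue positions.
#' @return Numeric vector of normalized conservation values (`NA` = missing).
#' @export
normalize_conservation <- function(profile, position) {
  stopifnot(inherits(profile, "conservation_profile"))
  mode <- attr(profile, "mode")
  idx <- match(as.integer(position), profile$position)
  raw <- profile$raw[idx]
  out <- switch(mode,
    grade = (raw - 1) / 8,
    continuous = {
      rng <- range(profile$raw)
      if (diff(rng) == 0) rep(0.5, length(raw))
      else (raw - rng[1]) / diff(rng)
    },
    fixture = {
      present <- raw[!is.na(raw)]
      if (any(present < -1 | present > 1)) {
        abort("fixture conservation values must lie in [-1, 1]",
              class = "mutriage_error_evidence")
      }
      if (any(present < 0)) {
        warn("fixture conservation value(s) outside [0, 1]")
      }
      raw
    })
  unname(out)
}

#' Serialize evidence tables back to TSV
#'
#' Content-preserving round-trip writers for the two evidence kinds.
#'
#' @param evidence Tibble from [load_pathogenicity()] or a
#'   `conservation_profile`.
#' @param path Output file.
#' @export
write_evidence <- function(evidence, path) {
  if (inherits(evidence, "conservation_profile")) {
    col <- switch(attr(evidence, "mode"),
                  grade = "grade", continuous = "score", fixture = "value")
    out <- tibble(position = evidence$position)
    out[[col]] <- evidence$raw
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_tsv(as_tibble(evidence), path, progress = FALSE)
  }
  invisible(path)
}
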