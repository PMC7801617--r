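## scoring_rank: feature composition, weighted final score, least-squares
## weight calibration, ranking and candidate selection.

#' Canonical feature names of the composite score
#'
#' Order of the feature vector entering the final score: external
#' pathogenicity probability, normalized BLOSUM62 penalty, normalized
#' conformation-matrix penalty, normalized conservation, and four binary
#' indicators (buried, between-helices, polarity change, binding-site
#' proximity).
#'
#' @format Character vector of length 8.
#' @export
FEATURE_NAMES <- c("pon_p2", "blosum_norm", "cbsm_norm", "consurf_norm",
                   "buried", "between_helices", "polarity_changed",
                   "site_proximal")

#' Construct composite-score weights
#'
#' A `score_weights` object is a named numeric vector: `intercept` plus one
#' coefficient per entry of [FEATURE_NAMES].
#'
#' @param intercept Intercept term.
#' @param ... Coefficients named after [FEATURE_NAMES]; unnamed features
#'   default to 0.
#' @param provenance `"user"` or `"fitted"`.
#' @export
score_weights <- function(intercept = 0, ..., provenance = "user") {
  dots <- c(...)
  bad <- setdiff(names(dots), FEATURE_NAMES)
  if (length(bad) > 0) {
    abort(sprintf("unknown weight name(s): %s", paste(bad, collapse = ", ")),
          class = "mutriage_error_weights")
  }
  w <- setNames(rep(0, length(FEATURE_NAMES)), FEATURE_NAMES)
  w[names(dots)] <- dots
  w <- c(intercept = unname(intercept), w)
  if (any(!is.finite(w))) {
    abort("weights must be finite", class = "mutriage_error_weights")
  }
  structure(w, provenance = provenance, class = "score_weights")
}

#' @export
print.score_weights <- function(x, ...) {
  cat("<score_weights>", attr(x, "provenance"), "\n")
  print(round(unclass(x), 4))
  if (!is.null(attr(x, "rank"))) cat("design rank:", attr(x, "rank"), "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects the tunable knobs of the triage pipeline.
#'
#' @param scheme Matrix-normalization scheme, `"fixture"` or `"row_range"`
#'   (see [normalize_substitution()]).
#' @param norm_fixture Normalized-score table for the fixture scheme.
#' @param rsa_threshold Buried/surface rsa cutoff.
#' @param window Binding-site proximity window (residues).
#' @param missing Missing-evidence policy: `"fail"` (default), `"drop"`, or
#'   `"impute"`.
#' @param impute Named numeric of neutral values used under
#'   `missing = "impute"`.
#' @param polarity_scheme Amino-acid polarity scheme.
#' @export
triage_config <- function(scheme = c("fixture", "row_range"),
                          norm_fixture = NULL,
                          rsa_threshold = 0.20,
                          window = 10L,
                          missing = c("fail", "drop", "impute"),
                          impute = c(pon_p2 = 0.5, blosum_norm = 0.5,
                                     cbsm_norm = 0.5, consurf_norm = 0.5,
                                     buried = 0, between_helices = 0),
                          polarity_scheme = POLARITY_DEFAULT) {
  list(scheme = match.arg(scheme), norm_fixture = norm_fixture,
       rsa_threshold = rsa_threshold, window = as.integer(window),
       missing = match.arg(missing), impute = impute,
       polarity_scheme = polarity_scheme)
}

## fixture-scheme normalization returning NA (not an error) on misses,
## so the missing-evidence policy can decide
norm_fixture_or_na <- function(wt, mut, mname, fixture) {
  if (is.null(fixture)) return(rep(NA_real_, length(wt)))
  idx <- match(paste(wt, mut, mname),
               paste(fixture$wt, fixture$mut, fixture$matrix))
  fixture$value[idx]
}

#' Compose the evidence feature vector for each catalog record
#'
#' Resolves, for every mutation, the eight features of [FEATURE_NAMES] from
#' the annotation, the substitution matrices and the evidence tables, plus
#' descriptive columns (domain, location label, nearest binding site and
#' distance, polarity-transition class) and the provenance of each evidence
#' source. Deterministic given its inputs.
#'
#' @param catalog Validated catalog tibble.
#' @param annotation `protein_annotation` with an environment table (or rsa).
#' @param blosum,cbsm `substitution_matrix` objects.
#' @param pathogenicity Tibble from [load_pathogenicity()].
#' @param conservation A `conservation_profile`.
#' @param config A [triage_config()].
#' @return Tibble: catalog columns, features, descriptors, provenance.
#' @export
compose_features <- function(catalog, annotation, blosum, cbsm,
                             pathogenicity, conservation,
                             config = triage_config()) {
  n <- nrow(catalog)
  if (n == 0L) {
    abort("empty catalog", class = "mutriage_error_pipeline")
  }
  pon <- pathogenicity$probability[match(catalog$id, pathogenicity$id)]
  if (config$scheme == "row_range") {
    bl <- normalize_substitution(catalog$wt_aa, catalog$mut_aa, blosum,
                                 scheme = "row_range")
    cb <- normalize_substitution(catalog$wt_aa, catalog$mut_aa, cbsm,
                                 scheme = "row_range")
  } else {
    bl <- norm_fixture_or_na(catalog$wt_aa, catalog$mut_aa,
                             attr(blosum, "name"), config$norm_fixture)
    cb <- norm_fixture_or_na(catalog$wt_aa, catalog$mut_aa,
                             attr(cbsm, "name"), config$norm_fixture)
  }
  cons <- normalize_conservation(conservation, catalog$position)
  env <- annotation$environment
  if (is.null(env)) {
    cls <- rep(NA_character_, n); bh <- rep(NA_integer_, n)
    loc_src <- rep(NA_character_, n)
  } else {
    idx <- match(catalog$position, env$position)
    cls <- env$location_class[idx]
    rsa <- env$rsa[idx]
    from_rsa <- is.na(cls) & !is.na(rsa)
    cls[from_rsa] <- ifelse(rsa[from_rsa] < config$rsa_threshold,
                            "buried", "surface")
    bh <- as.integer(env$bh[idx] %in% 1L)
    bh[is.na(idx)] <- NA_integer_
    loc_src <- ifelse(from_rsa, "rsa", "table")
  }
  pol_class <- polarity_transition(catalog$wt_aa, catalog$mut_aa,
                                   config$polarity_scheme)
  prox <- binding_site_proximity(catalog$position, annotation,
                                 window = config$window)
  feats <- tibble(
    id = catalog$id, wt_aa = catalog$wt_aa, position = catalog$position,
    mut_aa = catalog$mut_aa,
    recurrence = catalog$recurrence %||% rep(1L, n),
    tissue = catalog$tissue %||% rep(NA_character_, n),
    histology = catalog$histology %||% rep(NA_character_, n),
    domain = locate_domain(catalog$position, annotation),
    location_class = cls,
    pon_p2 = pon, blosum_norm = bl, cbsm_norm = cb, consurf_norm = cons,
    buried = as.numeric(cls == "buried"),
    between_helices = as.numeric(bh),
    polarity_changed = as.numeric(pol_class != "none"),
    site_proximal = as.numeric(prox$is_proximal),
    polarity_class = pol_class,
    nearest_site = prox$nearest_site,
    site_distance = prox$distance,
    pathogenicity_source = "file",
    matrix_source = config$scheme,
    conservation_source = attr(conservation, "mode"),
    location_source = loc_src)
  apply_missing_policy(feats, config)
}

## enforce the missing-evidence policy over the feature columns
apply_missing_policy <- function(feats, config) {
  check <- c("pon_p2", "blosum_norm", "cbsm_norm", "consurf_norm",
             "buried", "between_helices")
  nas <- is.na(as.matrix(feats[check]))
  any_na <- rowSums(nas) > 0
  if (!any(any_na)) return(feats)
  if (config$missing == "fail") {
    detail <- vapply(which(any_na), function(i) {
      sprintf("%s (%s)", feats$id[i],
              paste(check[nas[i, ]], collapse = ", "))
    }, character(1))
    abort(paste0("missing evidence under policy 'fail': ",
                 paste(detail, collapse = "; ")),
          class = "mutriage_error_missing_evidence")
  }
  if (config$missing == "drop") {
    message(sprintf("compose_features: dropped %d record(s) with missing evidence",
                    sum(any_na)))
    return(feats[!any_na, , drop = FALSE])
  }
  for (col in check) {
    miss <- is.na(feats[[col]])
    if (any(miss)) feats[[col]][miss] <- unname(config$impute[col])
  }
  feats
}

#' Final composite score
#'
#' `intercept + sum(weights * features)`; linear, hence monotone in every
#' feature with a non-negative coefficient.
#'
#' @param features Tibble containing the [FEATURE_NAMES] columns.
#' @param weights A [score_weights()] object.
#' @return Numeric vector of final scores.
#' @export
final_score <- function(features, weights) {
  stopifnot(inherits(weights, "score_weights"))
  X <- as.matrix(features[FEATURE_NAMES])
  storage.mode(X) <- "double"
  drop(X %*% unclass(weights)[FEATURE_NAMES]) + unclass(weights)[["intercept"]]
}

#' Calibrate composite-score weights by least squares
#'
#' Fits the intercept and the eight feature coefficients to reference final
#' scores by ordinary least squares. Rank-deficient designs are solved by
#' the minimum-norm Moore-Penrose pseudo-inverse, with the design rank
#' recorded on the result. A per-row residual report (target, fitted,
#' residual) is attached as attribute `"residual_report"`.
#'
#' @param features Tibble containing the [FEATURE_NAMES] columns (>= 2 rows).
#' @param targets Numeric vector of reference scores, one per row.
#' @return A `score_weights` with provenance `"fitted"`.
#' @export
fit_weights <- function(features, targets) {
  if (nrow(features) < 2L) {
    abort("weight calibration needs at least 2 rows",
          class = "mutriage_error_weights")
  }
  if (length(targets) != nrow(features) || any(!is.finite(targets))) {
    abort("targets must be finite, one per feature row",
          class = "mutriage_error_weights")
  }
  X <- cbind(intercept = 1, as.matrix(features[FEATURE_NAMES]))
  storage.mode(X) <- "double"
  qrX <- qr(X)
  rank <- qrX$rank
  if (rank == ncol(X)) {
    beta <- qr.coef(qrX, targets)
  } else {
    message(sprintf("fit_weights: rank-deficient design (rank %d of %d); minimum-norm solution",
                    rank, ncol(X)))
    beta <- drop(MASS::ginv(X) %*% targets)
    names(beta) <- colnames(X)
  }
  w <- structure(beta, provenance = "fitted", class = "score_weights")
  fitted <- drop(X %*% beta)
  attr(w, "rank") <- rank
  attr(w, "residual_report") <- tibble(
    id = if ("id" %in% names(features)) features$id else seq_along(targets),
    target = targets, fitted = fitted, residual = fitted - targets)
  w
}

#' Rank and select candidate mutations
#'
#' Selection takes every mutation scoring at or above the threshold, plus an
#' explicit manual-include list (mirroring curator overrides of borderline
#' scores). Output is sorted by final score, descending, with ties broken by
#' catalog order (stable).
#'
#' @param scored Tibble with `id` and `final_score` columns.
#' @param threshold Selection threshold (default 7.4).
#' @param manual_include Character vector of ids to force-include.
#' @return `scored` reordered, with `selected` (logical) and
#'   `selection_reason` (`above_threshold` / `manual_include` /
#'   `below_threshold`).
#' @export
select_candidates <- function(scored, threshold = 7.4,
                              manual_include = character()) {
  missing_ids <- setdiff(manual_include, scored$id)
  if (length(missing_ids) > 0) {
    abort(sprintf("manual include(s) absent from catalog: %s",
                  paste(missing_ids, collapse = ", ")),
          class = "mutriage_error_selection")
  }
  reason <- ifelse(scored$final_score >= threshold, "above_threshold",
                   "below_threshold")
  reason[scored$id %in% manual_include & reason == "below_threshold"] <-
    "manual_include"
  scored$selected <- reason %in% c("above_threshold", "manual_include")
  scored$selection_reason <- reason
  scored[order(-scored$final_score, seq_len(nrow(scored))), , drop = FALSE]
}

#' Run the full triage pipeline
#'
#' End to end: load and validate the catalog against the reference sequence,
#' compose evidence features, score (with supplied or calibrated weights),
#' rank and select. Fully deterministic given its inputs. Each argument
#' accepts either a loaded object or a file path.
#'
#' @param catalog Catalog tibble or path to a delimited catalog file.
#' @param reference `reference_sequence` or FASTA path.
#' @param annotation `protein_annotation` or YAML path.
#' @param environment Optional environment-table path (when `annotation` is
#'   a path).
#' @param blosum,cbsm Matrices or matrix-file paths.
#' @param pathogenicity Evidence tibble or path.
#' @param conservation `conservation_profile` or path.
#' @param weights A [score_weights()]; `NULL` to calibrate.
#' @param calibrate_targets Named numeric (id -> reference score) used to
#'   fit weights when `weights` is `NULL`.
#' @param config A [triage_config()].
#' @param threshold,manual_include Passed to [select_candidates()].
#' @return Report tibble (one row per mutation, ranked), with the weights
#'   used as attribute `"weights"` and the validation report as attribute
#'   `"validation"`.
#' @export
run_pipeline <- function(catalog, reference, annotation, environment = NULL,
                         blosum = blosum62_matrix(),
                         cbsm = cbsm60_synthetic_matrix(),
                         pathogenicity, conservation,
                         weights = NULL, calibrate_targets = NULL,
                         config = triage_config(),
                         threshold = 7.4, manual_include = character()) {
  if (is.character(reference)) reference <- load_reference(reference)
  if (is.character(annotation)) {
    annotation <- load_annotation(annotation, environment = environment)
  }
  if (is.character(catalog)) catalog <- load_catalog(catalog)
  if (is.character(blosum)) blosum <- read_substitution_matrix(blosum)
  if (is.character(cbsm)) cbsm <- read_substitution_matrix(cbsm)
  if (is.character(pathogenicity)) pathogenicity <- load_pathogenicity(pathogenicity)
  if (is.character(conservation)) conservation <- load_conservation(conservation)

  catalog <- validate_catalog(catalog, reference)
  validation <- attr(catalog, "report")
  feats <- compose_features(catalog, annotation, blosum, cbsm,
                            pathogenicity, conservation, config)
  if (is.null(weights)) {
    if (is.null(calibrate_targets)) {
      abort("either weights or calibrate_targets must be supplied",
            class = "mutriage_error_pipeline")
    }
    tgt <- calibrate_targets[feats$id]
    if (anyNA(tgt)) {
      abort("calibrate_targets must cover every scored mutation",
            class = "mutriage_error_pipeline")
    }
    weights <- fit_weights(feats, unname(tgt))
  }
  feats$final_score <- final_score(feats, weights)
  report <- select_candidates(feats, threshold = threshold,
                              manual_include = manual_include)
  report$location <- ifelse(report$between_helices == 1,
                            "BH/buried",
                            ifelse(report$location_class == "buried",
                                   "Buried", "Surface"))
  cols <- c("id", "recurrence", "tissue", "histology", "domain", "location",
            FEATURE_NAMES, "polarity_class", "nearest_site", "site_distance",
            "pathogenicity_source", "matrix_source", "conservation_source",
            "location_source", "final_score", "selected", "selection_reason")
  report <- report[, cols]
  attr(report, "weights") <- weights
  attr(report, "validation") <- validation
  report
}

#' Write a triage report as TSV
#'
#' Column order is fixed (see [run_pipeline()]); identical inputs produce
#' byte-identical files.
#'
#' @param report Report tibble.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path, progress = FALSE)
  invisible(path)
}

#' Ranking AUC of scores against binary labels
#'
#' Area under the ROC curve computed as the rank-sum (Mann-Whitney)
#' statistic: the probability that a randomly chosen positive outranks a
#' randomly chosen negative (ties count 1/2).
#'
#' @param score Numeric scores (higher = more suspect).
#' @param label Logical or 0/1 ground-truth labels.
#' @export
ranking_auc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) {
    abort("ranking_auc needs both positive and negative labels",
          class = "mutriage_error_selection")
  }
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
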