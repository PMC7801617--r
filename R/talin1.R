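## Bundled talin-1 reference case: the screened mutation catalog with its
## annotation, evidence fixtures, and printed reference triage outputs.

#' Paths to the bundled talin-1 fixture bundle
#'
#' The bundle carries the complete input set for the talin-1 reference
#' case: the mutation catalog (11 selected missense mutations with
#' recurrence and tissue metadata), the domain architecture and binding-site
#' registry, the per-residue environment table, per-mutation pathogenicity
#' probabilities and normalized conservation values as exported by the
#' external predictors, the normalized substitution-score fixture table, and
#' the printed reference triage outputs (domain, location, final score) used
#' as calibration targets. The reference sequence is a *synthetic stand-in*
#' (see file name) with the catalog's wild-type residues pinned at their
#' true positions.
#'
#' @return Named list of file paths: `catalog`, `reference`, `annotation`,
#'   `environment`, `pathogenicity`, `conservation`, `norm_scores`,
#'   `reference_scores`.
#' @export
talin1_bundle <- function() {
  p <- function(f) system.file("extdata", "talin1", f, package = "mutriage",
                               mustWork = TRUE)
  list(catalog = p("talin1_catalog.tsv"),
       reference = p("talin1_synthetic.fasta"),
       annotation = p("talin1_annotation.yaml"),
       environment = p("talin1_environment.tsv"),
       pathogenicity = p("talin1_ponp2.tsv"),
       conservation = p("talin1_consurf.tsv"),
       norm_scores = p("talin1_norm_scores.tsv"),
       reference_scores = p("talin1_reference_scores.tsv"))
}

#' Printed reference triage outputs for the talin-1 bundle
#'
#' @return Tibble with `id`, `domain`, `location`, `final_score`.
#' @export
talin1_reference_scores <- function() {
  readr::read_tsv(talin1_bundle()$reference_scores, comment = "#",
                  show_col_types = FALSE, progress = FALSE)
}

#' Run the triage pipeline on the bundled talin-1 case
#'
#' Convenience wrapper: loads the bundle, calibrates weights against the
#' printed reference final scores (unless `weights` is supplied) and returns
#' the ranked report with threshold 7.4 and the documented manual include
#' (`E1770Q`, kept despite a lower score for its location in the
#' autoinhibition site).
#'
#' @param weights Optional [score_weights()]; `NULL` calibrates by least
#'   squares against the bundled reference scores.
#' @param threshold,manual_include Selection parameters.
#' @return Ranked report tibble (see [run_pipeline()]).
#' @export
talin1_pipeline <- function(weights = NULL, threshold = 7.4,
                            manual_include = "E1770Q") {
  b <- talin1_bundle()
  ref_scores <- talin1_reference_scores()
  run_pipeline(
    catalog = b$catalog, reference = b$reference,
    annotation = b$annotation, environment = b$environment,
    pathogenicity = b$pathogenicity, conservation = b$conservation,
    weights = weights,
    calibrate_targets = setNames(ref_scores$final_score, ref_scores$id),
    config = triage_config(scheme = "fixture",
                           norm_fixture = load_norm_fixture(b$norm_scores)),
    threshold = threshold, manual_include = manual_include)
}
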