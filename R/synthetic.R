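## synthetic_data: fully self-contained synthetic studies (annotation,
## catalog, noisy predictor evidence, ground-truth labels) so every pipeline
## stage is testable without any download.

#' Configuration of a synthetic triage study
#'
#' Defaults emulate the talin-1 reference case: a 2541-residue multidomain
#' protein, a screened catalog of 258 missense mutations of which a small
#' fraction (11/258) carries a strong composite-evidence signal.
#'
#' @param protein_length Protein length in residues.
#' @param n_domains Number of contiguous domains tiling the protein.
#' @param n_binding_sites Number of short binding sites placed inside
#'   randomly chosen domains.
#' @param buried_fraction Fraction of residues drawn from the buried rsa
#'   regime.
#' @param bh_fraction Fraction of buried residues flagged between-helices.
#' @param n_mutations Catalog size.
#' @param pathogenic_fraction Expected share of ground-truth-pathogenic
#'   mutations (Bernoulli per mutation).
#' @param effect_weights Ground-truth [score_weights()] generating the true
#'   scores.
#' @param noise_sd Gaussian sd added to each simulated evidence value.
#' @param window Binding-site proximity window used for the true features.
#' @param logistic_scale Scale of the logistic link mapping structural score
#'   to true pathogenicity probability; `NULL` = 1/8 of the achievable
#'   structural-score range.
#' @param seed Integer seed; the same seed reproduces the study byte for
#'   byte.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(protein_length = 2541L,
                             n_domains = 19L,
                             n_binding_sites = 4L,
                             buried_fraction = 0.55,
                             bh_fraction = 0.3,
                             n_mutations = 258L,
                             pathogenic_fraction = 11 / 258,
                             effect_weights = score_weights(
                               intercept = 1, pon_p2 = 3.5,
                               blosum_norm = 0.5, cbsm_norm = 1,
                               consurf_norm = 1.2, buried = 1.2,
                               between_helices = 0.25,
                               polarity_changed = 0.5,
                               site_proximal = 0.5),
                             noise_sd = 0.05,
                             window = 10L,
                             logistic_scale = NULL,
                             seed = 1L) {
  cfg <- list(protein_length = as.integer(protein_length),
              n_domains = as.integer(n_domains),
              n_binding_sites = as.integer(n_binding_sites),
              buried_fraction = buried_fraction,
              bh_fraction = bh_fraction,
              n_mutations = as.integer(n_mutations),
              pathogenic_fraction = pathogenic_fraction,
              effect_weights = effect_weights,
              noise_sd = noise_sd,
              window = as.integer(window),
              logistic_scale = logistic_scale,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(protein_length > 0, n_domains > 0, n_mutations > 0,
              buried_fraction >= 0, buried_fraction <= 1,
              pathogenic_fraction >= 0, pathogenic_fraction <= 1,
              noise_sd >= 0, inherits(effect_weights, "score_weights"))
  })
  if (cfg$n_mutations > 19L * cfg$protein_length) {
    abort("infeasible config: more mutations than distinct substitutions",
          class = "mutriage_error_synthetic")
  }
  if (cfg$n_domains > cfg$protein_length) {
    abort("infeasible config: more domains than residues",
          class = "mutriage_error_synthetic")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic triage study
#'
#' Emits a complete input bundle into `dir`, in the same file dialects the
#' real loaders read: reference FASTA, annotation YAML, per-residue
#' environment TSV, mutation catalog TSV, pathogenicity and conservation
#' evidence TSVs, and a ground-truth TSV (true features, true probability,
#' true score, pathogenic label per mutation).
#'
#' Ground-truth-pathogenic mutations are sampled preferentially at
#' conserved, buried positions (half are additionally relocated next to a
#' binding site) and mutated to low-similarity residues; benign mutations
#' take conservative substitutions at weakly conserved surface positions.
#' The structural score (effect weights over the seven non-probability
#' features) is passed through a logistic link to give the true
#' pathogenicity probability; evidence files carry these truths plus
#' Gaussian noise (`noise_sd`).
#'
#' @param config A [synthetic_config()].
#' @param dir Target directory (created if needed).
#' @return List with `paths` (named file paths), `truth` (tibble),
#'   `weights` (the ground-truth weights) and `config`.
#' @export
generate_synthetic_study <- function(config = synthetic_config(),
                                     dir = tempfile("synthstudy")) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  L <- config$protein_length
  paths <- list(
    reference = file.path(dir, "synthetic_reference.fasta"),
    annotation = file.path(dir, "annotation.yaml"),
    environment = file.path(dir, "environment.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    pathogenicity = file.path(dir, "ponp2.tsv"),
    conservation = file.path(dir, "consurf.tsv"),
    truth = file.path(dir, "truth.tsv"))

  ## 1. reference sequence
  residues <- sample(AA_STANDARD, L, replace = TRUE)
  fa <- Biostrings::AAStringSet(paste(residues, collapse = ""))
  names(fa) <- sprintf("SYNTHETIC_PROTEIN length=%d seed=%d", L, config$seed)
  Biostrings::writeXStringSet(fa, paths$reference, width = 70)

  ## 2. domains tiling the protein
  nd <- config$n_domains
  cuts <- if (nd > 1) sort(sample(seq_len(L - 1), nd - 1)) else integer(0)
  dom_start <- c(1L, cuts + 1L)
  dom_end <- c(cuts, L)
  dom_name <- sprintf("D%02d", seq_len(nd))

  ## 3. binding sites: short intervals inside distinct random domains
  ns <- min(config$n_binding_sites, nd)
  host_idx <- sample(seq_len(nd), ns)
  resample1 <- function(x) x[sample.int(length(x), 1)]
  sites <- lapply(seq_len(ns), function(k) {
    i <- host_idx[k]
    wmax <- dom_end[i] - dom_start[i] + 1L
    w <- resample1(seq_len(min(3L, wmax)))
    s <- resample1(seq(dom_start[i], dom_end[i] - w + 1L))
    list(name = sprintf("site%02d", k), host_domain = dom_name[i],
         intervals = list(c(s, s + w - 1L)))
  })
  yaml::write_yaml(list(
    protein = sprintf("SYNTHETIC_PROTEIN_seed%d", config$seed),
    length = L,
    domains = lapply(seq_len(nd), function(i) {
      list(name = dom_name[i], start = dom_start[i], end = dom_end[i])
    }),
    binding_sites = sites), paths$annotation)

  ## 4. per-residue environment: two Beta-shaped rsa regimes
  regime_buried <- runif(L) < config$buried_fraction
  rsa <- ifelse(regime_buried, rbeta(L, 1.5, 20), rbeta(L, 6, 2))
  loc_class <- ifelse(rsa < 0.20, "buried", "surface")
  bh <- as.integer(loc_class == "buried" & runif(L) < config$bh_fraction)
  readr::write_tsv(tibble(position = seq_len(L), location_class = loc_class,
                          bh = bh, rsa = rsa),
                   paths$environment, progress = FALSE)

  ## 5. true per-residue conservation (bimodal: conserved cores vs drifted
  ## surface)
  conserved_core <- runif(L) < 0.35
  cons_true <- ifelse(conserved_core, rbeta(L, 10, 2), rbeta(L, 2, 6))

  ann <- load_annotation(paths$annotation, environment = paths$environment)
  blosum <- blosum62_matrix()
  cbsm <- cbsm60_synthetic_matrix()

  ## 6. mutation sampling, biased by the ground-truth label
  pathogenic <- runif(config$n_mutations) < config$pathogenic_fraction
  site_res <- unlist(lapply(sites, function(s) {
    seq(s$intervals[[1]][1], s$intervals[[1]][2])
  }))
  w_path <- (0.02 + cons_true)^5 * (1 + 1.5 * (loc_class == "buried"))
  w_ben <- (1.02 - cons_true)^5 * (1 + 1.5 * (loc_class == "surface"))
  pick_mut <- function(wt, damaging) {
    row <- blosum[wt, setdiff(AA_STANDARD, wt)]
    ranked <- names(sort(row))          # most dissimilar first
    pool <- if (damaging) ranked[1:3] else rev(ranked)[1:4]
    sample(pool, 1)
  }
  seen <- character(0)
  pos <- integer(config$n_mutations)
  mut <- character(config$n_mutations)
  for (i in seq_len(config$n_mutations)) {
    repeat {
      if (pathogenic[i]) {
        p <- sample.int(L, 1, prob = w_path)
        if (length(site_res) > 0 && runif(1) < 0.5) {
          p <- clamp(site_res[sample.int(length(site_res), 1)] +
                       sample(seq(-config$window, config$window), 1), 1L, L)
        }
      } else {
        p <- sample.int(L, 1, prob = w_ben)
      }
      m <- pick_mut(residues[p], pathogenic[i])
      id <- format_substitution(residues[p], p, m)
      if (!(id %in% seen)) break
    }
    seen <- c(seen, id)
    pos[i] <- p
    mut[i] <- m
  }
  catalog <- tibble(
    wt_aa = residues[pos], position = pos, mut_aa = mut,
    id = seen,
    recurrence = 1L + rpois(config$n_mutations, 0.3),
    tissue = sample(c("Skin", "Liver", "Breast", "Pancreas",
                      "Large intestine"), config$n_mutations, replace = TRUE),
    histology = sample(c("Carcinoma", "Malignant melanoma", "Glioma"),
                       config$n_mutations, replace = TRUE))

  ## 7. true features via the same composition code path (noiseless
  ## evidence in memory; probability filled after the structural score)
  cons_profile <- structure(tibble(position = seq_len(L), raw = cons_true),
                            mode = "fixture",
                            class = c("conservation_profile", "tbl_df",
                                      "tbl", "data.frame"))
  dummy_pon <- tibble(id = catalog$id, probability = 0.5)
  feats <- compose_features(catalog, ann, blosum, cbsm, dummy_pon,
                            cons_profile,
                            triage_config(scheme = "row_range",
                                          window = config$window))
  w <- unclass(config$effect_weights)
  rest <- setdiff(FEATURE_NAMES, "pon_p2")
  s0 <- drop(as.matrix(feats[rest]) %*% w[rest]) + w[["intercept"]]
  pos_part <- sum(pmax(w[rest], 0))
  neg_part <- sum(pmin(w[rest], 0))
  center <- w[["intercept"]] + (pos_part + neg_part) / 2
  scale <- config$logistic_scale %||% ((pos_part - neg_part) / 8)
  p_true <- plogis((s0 - center) / scale)
  feats$pon_p2 <- p_true
  true_score <- final_score(feats, config$effect_weights)

  ## 8. noisy evidence files
  p_obs <- clamp(p_true + rnorm(config$n_mutations, 0, config$noise_sd), 0, 1)
  readr::write_tsv(tibble(id = catalog$id, probability = p_obs),
                   paths$pathogenicity, progress = FALSE)
  cons_obs <- cons_true + rnorm(L, 0, config$noise_sd)
  if (any(cons_obs < 0 | cons_obs > 1)) {
    cons_obs <- (cons_obs - min(cons_obs)) / (max(cons_obs) - min(cons_obs))
  }
  readr::write_tsv(tibble(position = seq_len(L), value = cons_obs),
                   paths$conservation, progress = FALSE)
  readr::write_tsv(
    tibble(mutation = catalog$id, recurrence = catalog$recurrence,
           primary_tissue = catalog$tissue, histology = catalog$histology),
    paths$catalog, progress = FALSE)

  truth <- feats[, c("id", "position", FEATURE_NAMES)]
  truth$pathogenic <- pathogenic
  truth$true_probability <- p_true
  truth$true_score <- true_score
  readr::write_tsv(truth, paths$truth, progress = FALSE)

  list(paths = paths, truth = truth, weights = config$effect_weights,
       config = config)
}
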