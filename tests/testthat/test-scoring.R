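talin_features <- function() {
  tl <- talin()
  cat <- validate_catalog(tl$catalog, tl$ref)
  compose_features(cat, tl$ann, blosum62_matrix(), cbsm60_synthetic_matrix(),
                   tl$pon, tl$cons,
                   triage_config(scheme = "fixture",
                                 norm_fixture = tl$fixture))
}

test_that("feature composition reproduces the bundled reference case", {
  feats <- talin_features()
  i392n <- feats[feats$id == "I392N", ]
  expect_equal(
    unlist(i392n[FEATURE_NAMES]),
    c(pon_p2 = 0.86, blosum_norm = 1, cbsm_norm = 0.83, consurf_norm = 1,
      buried = 1, between_helices = 0, polarity_changed = 1,
      site_proximal = 1))
  expect_equal(i392n$nearest_site, "integrin")
  ## proximity pattern over the whole catalog
  expect_equal(feats$id[feats$site_proximal == 1],
               c("I392N", "L1539P", "E1770Q", "L2509P"))
})

test_that("missing evidence follows the configured policy", {
  tl <- talin()
  cat <- tl$catalog
  pon_short <- tl$pon[tl$pon$id != "I392N", ]
  cfg <- triage_config(scheme = "fixture", norm_fixture = tl$fixture)
  expect_error(compose_features(cat, tl$ann, blosum62_matrix(),
                                cbsm60_synthetic_matrix(), pon_short,
                                tl$cons, cfg),
               class = "mutriage_error_missing_evidence")
  cfg$missing <- "drop"
  expect_message(
    dropped <- compose_features(cat, tl$ann, blosum62_matrix(),
                                cbsm60_synthetic_matrix(), pon_short,
                                tl$cons, cfg),
    "dropped 1")
  expect_equal(nrow(dropped), 10L)
  cfg$missing <- "impute"
  imputed <- compose_features(cat, tl$ann, blosum62_matrix(),
                              cbsm60_synthetic_matrix(), pon_short,
                              tl$cons, cfg)
  expect_equal(imputed$pon_p2[imputed$id == "I392N"], 0.5)
})

test_that("the final score is the affine combination of the features", {
  feats <- talin_features()
  expect_equal(final_score(feats, score_weights(intercept = 7)),
               rep(7, nrow(feats)))
  unit <- do.call(score_weights,
                  c(list(intercept = 0), setNames(as.list(rep(1, 8)),
                                                  FEATURE_NAMES)))
  one_row <- tibble::as_tibble(setNames(
    as.list(c(0.5, 0.5, 0, 0, 1, 0, 0, 0)), FEATURE_NAMES))
  expect_equal(final_score(one_row, unit), 2.0)
  ## invariant to catalog row order
  perm <- sample(nrow(feats))
  expect_equal(final_score(feats, unit)[perm],
               final_score(feats[perm, ], unit))
})

test_that("non-negative weights make the score monotone in each feature", {
  w <- score_weights(intercept = 1, pon_p2 = 3.5, blosum_norm = 0.5,
                     cbsm_norm = 1, consurf_norm = 1.2, buried = 1.2,
                     between_helices = 0.25, polarity_changed = 0.5,
                     site_proximal = 0.5)
  base <- tibble::as_tibble(setNames(as.list(rep(0.3, 8)), FEATURE_NAMES))
  s0 <- final_score(base, w)
  for (f in FEATURE_NAMES) {
    for (delta in c(0.1, 0.4, 0.7)) {
      up <- base
      up[[f]] <- up[[f]] + delta
      expect_gte(final_score(up, w), s0)
    }
  }
})

test_that("least squares recovers exact generating weights", {
  set.seed(11)
  n <- 40
  X <- tibble::as_tibble(setNames(as.list(as.data.frame(
    matrix(runif(n * 8), n))), FEATURE_NAMES))
  X$buried <- round(X$buried)
  w_true <- score_weights(intercept = 2, pon_p2 = 3, blosum_norm = -1,
                          cbsm_norm = 0.5, consurf_norm = 1, buried = 0.7,
                          between_helices = 0.2, polarity_changed = 0.1,
                          site_proximal = 0.4)
  y <- final_score(X, w_true)
  w_hat <- fit_weights(X, y)
  expect_lt(max(abs(unclass(w_hat) - unclass(w_true))), 1e-8)
  expect_equal(attr(w_hat, "rank"), 9L)
  expect_lt(max(abs(attr(w_hat, "residual_report")$residual)), 1e-8)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  X <- tibble::as_tibble(setNames(as.list(as.data.frame(
    matrix(c(0.1, 0.5, 0.9, 0.2, 0.4, 0.8, rep(0, 18)), 3))), FEATURE_NAMES))
  y <- c(1, 2, 3)
  expect_message(w <- fit_weights(X, y), "rank-deficient")
  expect_equal(attr(w, "rank"), 3L)
  ## the fit interpolates: targets lie in the design column space
  Xm <- cbind(1, as.matrix(X))
  expect_equal(drop(Xm %*% unclass(w)), y, tolerance = 1e-10)
  ## minimum-norm oracle: pseudo-inverse built directly from the SVD
  sv <- svd(Xm)
  keep <- sv$d > max(dim(Xm)) * .Machine$double.eps * sv$d[1]
  beta_svd <- sv$v[, keep] %*% ((t(sv$u[, keep]) %*% y) / sv$d[keep])
  expect_equal(as.numeric(unclass(w)), drop(beta_svd), tolerance = 1e-10)
})

test_that("calibration inputs are validated", {
  X <- tibble::as_tibble(setNames(as.list(rep(0.5, 8)), FEATURE_NAMES))
  expect_error(fit_weights(X, 1), class = "mutriage_error_weights")
  X2 <- dplyr::bind_rows(X, X)
  expect_error(fit_weights(X2, c(1, NA)), class = "mutriage_error_weights")
})

test_that("selection honors the threshold plus manual includes", {
  ref <- talin1_reference_scores()
  scored <- tibble::tibble(id = ref$id, final_score = ref$final_score)
  sel <- select_candidates(scored, threshold = 7.4,
                           manual_include = "E1770Q")
  expect_equal(sum(sel$selected), 11L)
  expect_equal(sel$selection_reason[sel$id == "E1770Q"], "manual_include")
  expect_equal(sum(sel$selection_reason == "above_threshold"), 10L)
  expect_equal(sel$final_score, sort(sel$final_score, decreasing = TRUE))

  all_sel <- select_candidates(scored, threshold = 0)
  expect_true(all(all_sel$selected))
  expect_error(select_candidates(scored, manual_include = "Z9Z"),
               class = "mutriage_error_selection")
  ## stable tie-break by catalog order
  ties <- tibble::tibble(id = c("A1B", "C2D", "E3F"),
                         final_score = c(5, 5, 5))
  expect_equal(select_candidates(ties, threshold = 4)$id, ties$id)
})

test_that("the pipeline is deterministic end to end", {
  dir <- withr::local_tempdir()
  r1 <- suppressMessages(talin1_pipeline())
  r2 <- suppressMessages(talin1_pipeline())
  f1 <- file.path(dir, "r1.tsv"); f2 <- file.path(dir, "r2.tsv")
  write_report(r1, f1); write_report(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
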