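test_that("substitution tokens parse across dialects and case", {
  p <- parse_substitution(c("L2509P", "p.I392N", "p.Leu1539Pro", "v577d"))
  expect_equal(p$wt_aa, c("L", "I", "L", "V"))
  expect_equal(p$position, c(2509L, 392L, 1539L, 577L))
  expect_equal(p$mut_aa, c("P", "N", "P", "D"))
  expect_equal(p$id, c("L2509P", "I392N", "L1539P", "V577D"))
})

test_that("parse errors are distinct, named conditions", {
  expect_error(parse_substitution("p.A5A"), class = "mutriage_error_synonymous")
  expect_error(parse_substitution("X999Z"),
               class = "mutriage_error_nonstandard_aa")
  expect_error(parse_substitution("L25"), class = "mutriage_error_malformed")
  expect_error(parse_substitution("p.Xyz12Ala"),
               class = "mutriage_error_nonstandard_aa")
})

test_that("parse -> format -> parse is the identity on random valid ids", {
  set.seed(42)
  ids <- unique(random_valid_ids(1000))
  back <- parse_substitution(ids)
  expect_identical(back$id, ids)
  expect_identical(format_substitution(back$wt_aa, back$position, back$mut_aa),
                   ids)
})

test_that("bundled talin-1 catalog loads with 11 records in table order", {
  tl <- talin()
  expect_equal(nrow(tl$catalog), 11L)
  expect_identical(tl$catalog$id, talin_expected()$id)
  expect_equal(tl$catalog$recurrence[tl$catalog$id == "A893E"], 3L)
  expect_equal(sum(attr(tl$catalog, "dropped")), 0L)
})

test_that("non-missense rows are dropped with a tally; order preserved", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutation\trecurrence\tprimary_tissue\thistology",
               "A10V\t1\tSkin\tCarcinoma",
               "Q54*\t2\tSkin\tCarcinoma",
               "L77P\t1\tLiver\tCarcinoma",
               "p.G12fs\t1\tLiver\tCarcinoma",
               "K90E\t1\tBreast\tCarcinoma"), f)
  expect_message(cat <- load_catalog(f), "dropped 2 non-missense")
  expect_equal(cat$id, c("A10V", "L77P", "K90E"))
  expect_equal(sum(attr(cat, "dropped")), 2L)
  expect_equal(unname(attr(cat, "dropped")["nonsense"]), 1L)
  expect_equal(unname(attr(cat, "dropped")["frameshift"]), 1L)
})

test_that("empty catalog with header yields an empty list", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("mutation\trecurrence\tprimary_tissue\thistology", f)
  expect_equal(nrow(load_catalog(f)), 0L)
})

test_that("duplicate ids merge by summing recurrence", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mutation\trecurrence\tprimary_tissue\thistology",
               "A10V\t2\tSkin\tCarcinoma",
               "L77P\t1\tLiver\tCarcinoma",
               "A10V\t3\tBreast\tCarcinoma"), f)
  cat <- load_catalog(f)
  expect_equal(cat$id, c("A10V", "L77P"))
  expect_equal(cat$recurrence, c(5L, 1L))
  expect_equal(cat$tissue[1], "Skin/Breast")
})

test_that("missing configured columns raise an io error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mut\trecurrence", "A10V\t1"), f)
  expect_error(load_catalog(f), class = "mutriage_error_io")
})

test_that("validation checks range and wild-type identity against reference", {
  tl <- talin()
  ok <- validate_catalog(tl$catalog, tl$ref)
  expect_equal(nrow(ok), 11L)
  expect_equal(nrow(attr(ok, "report")), 0L)

  boundary <- parse_substitution(
    format_substitution(tl$ref$residues[2541],
                        2541,
                        setdiff(AA_STANDARD, tl$ref$residues[2541])[1]))
  boundary$recurrence <- 1L; boundary$tissue <- NA; boundary$histology <- NA
  kept <- validate_catalog(boundary, tl$ref)
  expect_equal(nrow(kept), 1L)

  bad <- tibble::tibble(wt_aa = c("A", "L"), position = c(2542L, 2509L),
                        mut_aa = c("V", "V"),
                        id = c("A2542V", "L2509V"),
                        recurrence = 1L, tissue = NA, histology = NA)
  bad$wt_aa[2] <- "G"   # reference residue 2509 is L, not G
  bad$id[2] <- "G2509V"
  out <- validate_catalog(bad, tl$ref)
  rep <- attr(out, "report")
  expect_equal(nrow(out), 0L)
  expect_setequal(rep$failure, c("out_of_range", "wt_mismatch"))
  expect_match(rep$detail[rep$failure == "wt_mismatch"], "G")
  expect_match(rep$detail[rep$failure == "wt_mismatch"], "L")
})

test_that("validated catalogs never violate record invariants", {
  tl <- talin()
  cat <- validate_catalog(tl$catalog, tl$ref)
  expect_true(all(cat$wt_aa != cat$mut_aa))
  expect_true(all(cat$wt_aa %in% AA_STANDARD & cat$mut_aa %in% AA_STANDARD))
  expect_true(all(cat$position >= 1L & cat$position <= tl$ref$length))
  expect_true(all(cat$recurrence >= 0L))
})

test_that("catalog and validation report serialize as TSV", {
  tl <- talin()
  cat <- validate_catalog(tl$catalog, tl$ref)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(cat, f1)
  write_validation_report(cat, f2)
  back <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_equal(back$id, cat$id)
  expect_equal(nrow(readr::read_tsv(f2, show_col_types = FALSE)), 0L)
})
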