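test_that("bundled talin-1 annotation carries the full domain architecture", {
  tl <- talin()
  expect_equal(length(unique(tl$ann$domains$name)), 19L)
  expect_equal(nrow(tl$ann$domains), 20L)      # R7 is discontinuous
  expect_setequal(unique(tl$ann$sites$site),
                  c("integrin", "DLC-1", "autoinhibition", "ABS3"))
})

test_that("domain lookup matches the reference assignments", {
  tl <- talin()
  expect_equal(locate_domain(392, tl$ann), "F3")
  expect_equal(locate_domain(1539, tl$ann), "R8")
  expect_equal(locate_domain(2509, tl$ann), "DD")
  expect_equal(locate_domain(440, tl$ann), "linker")
  ## discontinuous R7: both segments resolve to R7, the inserted R8 does not
  expect_equal(locate_domain(c(1368, 1600, 1500), tl$ann),
               c("R7", "R7", "R8"))
  ## all 11 bundled mutations map to their printed domain
  exp <- talin_expected()
  expect_equal(locate_domain(tl$catalog$position, tl$ann), exp$domain)
})

test_that("positions outside the sequence are rejected", {
  tl <- talin()
  expect_error(locate_domain(0, tl$ann), class = "mutriage_error_annotation")
  expect_error(locate_domain(2542, tl$ann),
               class = "mutriage_error_annotation")
})

test_that("invalid annotation files are rejected at load", {
  dir <- withr::local_tempdir()
  overlapping <- file.path(dir, "bad1.yaml")
  yaml::write_yaml(list(protein = "x", length = 100, domains = list(
    list(name = "A", start = 1, end = 50),
    list(name = "B", start = 40, end = 100)), binding_sites = list()),
    overlapping)
  expect_error(load_annotation(overlapping),
               class = "mutriage_error_annotation")

  outside <- file.path(dir, "bad2.yaml")
  yaml::write_yaml(list(protein = "x", length = 100, domains = list(
    list(name = "A", start = 1, end = 50)), binding_sites = list(
    list(name = "s", host_domain = "A", residues = list(99)))), outside)
  expect_error(load_annotation(outside), class = "mutriage_error_annotation")

  inverted <- file.path(dir, "bad3.yaml")
  yaml::write_yaml(list(protein = "x", length = 100, domains = list(
    list(name = "A", start = 30, end = 10)), binding_sites = list()),
    inverted)
  expect_error(load_annotation(inverted), class = "mutriage_error_annotation")
})

test_that("explicit-table location classification is passed through", {
  tl <- talin()
  cls <- classify_location(c(392, 229, 1368), tl$ann)
  expect_equal(cls$location_class, c("buried", "buried", "surface"))
  expect_equal(cls$between_helices, c(0L, 1L, 0L))
  expect_error(classify_location(5, tl$ann),
               class = "mutriage_error_missing_evidence")
})

test_that("rsa mode classifies by threshold and is monotone in rsa", {
  dir <- withr::local_tempdir()
  ya <- file.path(dir, "ann.yaml")
  yaml::write_yaml(list(protein = "x", length = 101, domains = list(
    list(name = "A", start = 1, end = 101)), binding_sites = list()), ya)
  rsa_grid <- seq(0, 1, by = 0.01)
  env <- file.path(dir, "env.tsv")
  readr::write_tsv(tibble::tibble(position = seq_along(rsa_grid),
                                  location_class = NA_character_,
                                  bh = 0L, rsa = rsa_grid), env)
  ann <- load_annotation(ya, environment = env)
  cls <- classify_location(seq_along(rsa_grid), ann, rsa_threshold = 0.20)
  expect_equal(cls$location_class[rsa_grid == 0], "buried")
  expect_equal(cls$location_class[rsa_grid == 1], "surface")
  ## monotone: lowering rsa never flips buried -> surface
  buried <- cls$location_class == "buried"
  expect_true(all(diff(buried[order(rsa_grid)]) <= 0))
  expect_equal(cls$location_class, ifelse(rsa_grid < 0.20,
                                          "buried", "surface"))
})

test_that("binding-site proximity measures sequence separation", {
  tl <- talin()
  p <- binding_site_proximity(1539, tl$ann, window = 10)
  expect_true(p$is_proximal)
  expect_equal(p$nearest_site, "DLC-1")
  expect_equal(p$distance, 5)          # min(|1539-1530|, |1539-1544|)

  p <- binding_site_proximity(1770, tl$ann, window = 10)
  expect_true(p$is_proximal)
  expect_equal(p$nearest_site, "autoinhibition")
  expect_lte(p$distance, 10)

  far <- binding_site_proximity(1000, tl$ann, window = 10)
  expect_false(far$is_proximal)

  ## distance 0 iff the position lies inside a registered site
  inside <- binding_site_proximity(c(392, 1530, 2509), tl$ann)
  expect_equal(inside$distance, c(0, 0, 0))
  outside <- binding_site_proximity(c(384, 1531), tl$ann)
  expect_true(all(outside$distance > 0))
})

test_that("an empty site registry yields the infinite-distance sentinel", {
  dir <- withr::local_tempdir()
  ya <- file.path(dir, "ann.yaml")
  yaml::write_yaml(list(protein = "x", length = 50, domains = list(
    list(name = "A", start = 1, end = 50)), binding_sites = list()), ya)
  ann <- load_annotation(ya)
  p <- binding_site_proximity(25, ann)
  expect_false(p$is_proximal)
  expect_identical(p$distance, Inf)
})
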