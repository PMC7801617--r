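## shared helpers: bundled talin-1 objects and small synthetic studies

talin <- function() {
  b <- talin1_bundle()
  list(bundle = b,
       ref = load_reference(b$reference),
       ann = load_annotation(b$annotation, environment = b$environment),
       catalog = load_catalog(b$catalog),
       pon = load_pathogenicity(b$pathogenicity),
       cons = load_conservation(b$conservation),
       fixture = load_norm_fixture(b$norm_scores),
       ref_scores = talin1_reference_scores())
}

## printed reference component values for the bundled catalog, frozen in-test
talin_expected <- function() {
  tibble::tribble(
    ~id,      ~domain, ~location,   ~pon_p2, ~blosum_norm, ~cbsm_norm, ~consurf_norm,
    "P229L",  "F2",    "BH/buried", 0.94,    1,            1,          1,
    "I392N",  "F3",    "Buried",    0.86,    1,            0.83,       1,
    "V577D",  "R1",    "Buried",    0.94,    1,            1,          0.60,
    "A893E",  "R3",    "BH/buried", 0.95,    0.75,         0.33,       0.60,
    "R1368W", "R7",    "Surface",   0.98,    1,            1,          1,
    "Y1389C", "R7",    "Buried",    0.90,    0.87,         0.67,       1,
    "L1539P", "R8",    "Buried",    0.98,    1,            1,          0.60,
    "S1750F", "R9",    "Buried",    0.89,    0.87,         0.5,        0.60,
    "E1770Q", "R9",    "Surface",   0.81,    0.37,         -0.33,      1,
    "D2086V", "R11",   "Surface",   0.96,    1,            1,          1,
    "L2509P", "DD",    "Surface",   0.96,    1,            1,          0.64)
}

## load a generated synthetic study back through the real module loaders and
## compose its features
compose_study <- function(study, scheme = "row_range") {
  ann <- load_annotation(study$paths$annotation,
                         environment = study$paths$environment)
  catalog <- load_catalog(study$paths$catalog)
  compose_features(catalog, ann, blosum62_matrix(), cbsm60_synthetic_matrix(),
                   load_pathogenicity(study$paths$pathogenicity),
                   load_conservation(study$paths$conservation),
                   triage_config(scheme = scheme))
}

random_valid_ids <- function(n, max_pos = 99999L) {
  wt <- sample(AA_STANDARD, n, replace = TRUE)
  mut <- vapply(wt, function(a) sample(setdiff(AA_STANDARD, a), 1),
                character(1))
  pos <- sample.int(max_pos, n, replace = TRUE)
  format_substitution(wt, pos, mut)
}
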