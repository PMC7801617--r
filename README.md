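# mutriage

Missense mutation triage by composite evidence scoring.

Large cancer sequencing catalogs report hundreds of somatic missense
mutations per gene, far more than can be characterised experimentally.
`mutriage` implements a desk-scale screening pipeline for prioritising such
mutations in large multidomain proteins: each substitution is annotated with
a small set of normalized evidence features and the features are combined
into a single composite score used to rank candidates and pick a tractable
subset for follow-up. The bundled reference case is talin-1, the
2541-residue focal-adhesion scaffold (FERM head F0–F3, ~80-residue linker,
rod domains R1–R13, C-terminal dimerisation domain DD), screened for
cancer-associated point mutations.

## The scoring model

For mutation *i* the pipeline assembles a feature vector
*x<sub>i</sub>* = (p, b, c, s, B, H, P, L):

| feature | range | meaning |
|---|---|---|
| `pon_p2` (p) | [0,1] | externally predicted probability of pathogenicity |
| `blosum_norm` (b) | [−1,1] | normalized BLOSUM62 substitution penalty |
| `cbsm_norm` (c) | [−1,1] | normalized conformation-specific matrix penalty |
| `consurf_norm` (s) | [0,1] | normalized evolutionary conservation |
| `buried` (B) | 0/1 | residue buried in the fold |
| `between_helices` (H) | 0/1 | residue at a helix–helix interface |
| `polarity_changed` (P) | 0/1 | substitution changes polarity class |
| `site_proximal` (L) | 0/1 | within 10 residues of a known ligand-binding site |

and the final score is the affine combination

> score(*x*) = w₀ + **w** · *x*.

The weights **w** can be supplied directly, or calibrated by ordinary least
squares against a set of reference scores (`fit_weights()`; rank-deficient
designs fall back to the minimum-norm pseudo-inverse solution). Candidates
with score ≥ threshold (default 7.4) are selected; a manual-include list
mirrors curator overrides of borderline cases.

Matrix penalties come in two normalization schemes: a computable
`row_range` default, `(score(wt,wt) − score(wt,mut)) / (score(wt,wt) −
min(score(wt,·)))`, and a `fixture` scheme that carries externally computed
normalized values verbatim. Conservation is ingested as discrete grades
(1–9, mapped to (g−1)/8), continuous scores (min–max) or already-normalized
values; pathogenicity probabilities are read from predictor exports — the
package never calls external web services.

## Worked example: the bundled talin-1 case

```r
library(mutriage)
report <- talin1_pipeline()   # calibrates weights, scores, ranks, selects
report[1:3, c("id", "domain", "location", "pon_p2", "cbsm_norm", "final_score")]
#> # A tibble: 3 × 6
#>   id     domain location pon_p2 cbsm_norm final_score
#>   <chr>  <chr>  <chr>     <dbl>     <dbl>       <dbl>
#> 1 I392N  F3     Buried     0.86      0.83        8.96
#> 2 L1539P R8     Buried     0.98      1           8.55
#> 3 V577D  R1     Buried     0.94      1           8.42
attr(report, "weights")
#> <score_weights> fitted
#>        intercept           pon_p2      blosum_norm        cbsm_norm
#>           1.0092           3.6924           0.3165           1.1062
#>     consurf_norm           buried  between_helices polarity_changed
#>           1.2105           1.2291          -0.0742           0.5611
#>    site_proximal
#>           0.5422
```

The top-ranked mutation, I392N, is a buried hydrophobic-to-polar
substitution at a fully conserved position inside the integrin-activation
helix of F3 — every evidence channel is unfavourable, so it scores highest
(8.96). E1770Q, in contrast, scores 6.07 (conservative glutamate-to-glutamine
change on the R9 surface) and enters the selected set only through the
manual include that reflects its position in the talin autoinhibition site.

Synthetic studies with known ground truth are one call away:

```r
study <- generate_synthetic_study(synthetic_config(seed = 1))
names(study$paths)
#> [1] "reference" "annotation" "environment" "catalog"
#> [5] "pathogenicity" "conservation" "truth"
```

A thin command-line front end (`exec/mutriage`, subcommands `score`,
`select`, `simulate`) wraps the same functions for shell use.

Note: the bundled talin-1 FASTA is a *synthetic stand-in* sequence (catalog
wild-type residues pinned at their true positions), and the bundled
conformation-specific matrix is likewise a labelled synthetic stand-in; the
reference-case component values ship as real fixture tables.

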