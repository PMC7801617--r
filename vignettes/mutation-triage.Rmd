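---
title: "Composite evidence scoring for missense mutation triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite evidence scoring for missense mutation triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutriage)
```

## The problem and the model

Somatic mutation catalogs list hundreds of missense substitutions per gene
with no indication of which ones matter. For a large multidomain
mechanosensor like talin-1, only a handful can be characterised
biochemically, so the first stage of any study is a triage: convert cheap,
per-mutation evidence into a single ranking and cut it down to an
experimentally tractable set.

`mutriage` scores each substitution with an affine model over eight
normalized features,

$$\mathrm{score}(x) = w_0 + \sum_j w_j x_j,$$

with $x$ = (pathogenicity probability, BLOSUM62 penalty,
conformation-matrix penalty, conservation, buried, between-helices,
polarity-changed, site-proximal). The model is deliberately linear: the
evidence channels are weak individually and correlated with each other, and
a transparent weighted sum keeps every contribution auditable — the point
of a triage score is to justify a shortlist, not to estimate effect sizes.
Consequences of linearity are exploited in the tests: the score is
invariant to catalog order, and monotone in each feature whose weight is
non-negative.

## Evidence features and their normalization

**Substitution-matrix penalties.** Raw log-odds scores from BLOSUM62 and a
conformation-specific matrix are mapped to penalties by the `row_range`
scheme
$$\frac{s(wt,wt) - s(wt,mut)}{s(wt,wt) - \min_a s(wt,a)},$$
which is 0 at identity and 1 for the most penalized substitution in the
wild-type's row, making rows with different self-scores comparable. A
second, `fixture`, scheme reads normalized values verbatim from a table.
Both exist because published screens often report normalized penalties
whose exact normalization is not recoverable from the main text — the
bundled talin-1 values are internally inconsistent with any single
per-substitution rule (two substitutions with identical raw scores print
different normalized values), so the printed numbers are carried as data
rather than guessed as code. The `row_range` scheme is therefore *not*
asserted to reproduce the fixture values, and the reference-case
reproduction runs under `scheme = "fixture"`.

**Conservation.** Discrete grades $g \in 1..9$ map linearly to $(g-1)/8$;
continuous profiles are min–max scaled over the profile; already-normalized
values pass through verbatim (range-checked to $[-1,1]$ and flagged outside
$[0,1]$). A position absent from the profile is an explicit missing-evidence
marker, never a silent zero.

**Location.** Buried/surface comes either from an explicit per-residue
table (authoritative for the bundled case, where the assignment rule of the
original annotation is not recoverable) or from relative solvent
accessibility with the common rsa < 0.20 buried convention. The
between-helices flag is always annotation-supplied; no structural rule for
it is computed here. Structure parsing and accessibility computation are
out of scope by design — the package consumes annotations, it does not
derive them.

**Polarity.** The default scheme groups A,V,L,I,M,F,W,C,P,G as
hydrophobic, S,T,N,Q,Y,H as polar-uncharged, D,E and K,R as charged; the
binary feature fires when the class changes. The grouping is a replaceable
default (`POLARITY_DEFAULT`), chosen because helical-bundle stability is
dominated by the hydrophobic effect, so hydrophobic-to-polar transitions
are the transition of interest.

**Binding-site proximity.** Distance is minimum absolute *sequence*
separation to any registered site residue; the default window of 10
residues encodes "close to a known ligand-binding site" as a named knob
rather than a hidden constant. Sequence distance is a deliberate
simplification — residues close in space but far in sequence (e.g. a
mutation one domain away from an interface) are not captured, which is a
known limitation.

## Weight calibration

Published screens often obtain weights by manual iteration, which is not
reproducible. `fit_weights()` replaces the search with ordinary least
squares against reference final scores: deterministic, auditable, and
exactly recovering any weights whose targets lie in the design's column
space. With fewer rows than parameters the design is rank-deficient; the
minimum-norm Moore–Penrose solution is used and the rank is logged, so
calibration on small reference sets stays well-defined. On the bundled
11-row talin-1 reference the fit reproduces the printed final scores to a
maximum absolute residual of 0.23.

Selection applies a threshold (default 7.4, just below the lowest
above-threshold reference score) plus an explicit manual-include list; the
bundled case force-includes E1770Q, whose conservative surface substitution
scores low on every channel but sits in the talin autoinhibition site.
Ranking ties break by catalog order, for reproducibility.

## The talin-1 domain fixture

Domain boundaries are frozen from published construct and structure residue
ranges (head 1–405 with F2–F3 at 208–398 and F3 at 309–405; R1 487–656; R3
796–909; R7 discontinuous at 1352–1457 and 1585–1659 around the inserted
R8; R9 construct 1655–1822; R11 1975–2140; R13–DD 2300–2541 with DD
2494–2541), and gaps between anchors are closed by extending the earlier
domain to the next start − 1. Two consequences are documented per interval
in the fixture: the R7/R9 anchor ranges overlap by five residues (they are
expression constructs, not a partition), so R9 is trimmed to start at 1660;
and unanchored rod boundaries (R4–R6, R10, R12) are interpolated. The
binding-site registry carries only sites with published residue anchors:
the integrin-activation helix in F3 (385–405), the DLC-1 contacts K1530 and
K1544 in R8, an approximate autoinhibition patch in R9 (1761–1772, around
the autoinhibition-critical E1770), and the DD part of the C-terminal actin
binding site ABS3. The bundled FASTA is a synthetic stand-in sequence with
the catalog's wild-type residues pinned at their true positions, and the
bundled conformation-specific matrix is a synthetic stand-in with the
correct structure (symmetric, 20×20, similarity-like); both are labelled as
such in their files.

## The synthetic-study generator

`generate_synthetic_study()` emits a complete input bundle — reference
FASTA, annotation YAML, environment TSV, catalog TSV, two evidence TSVs and
a truth table — in exactly the dialects the loaders read, so the generator
doubles as format documentation. Defaults emulate the bundled study's
scale: a 2541-residue protein tiled by 19 domains, 258 catalog mutations,
pathogenic fraction 11/258.

The generative model: residues draw rsa from two Beta regimes
(Beta(1.5, 20) buried-like vs Beta(6, 2) surface-like, mixed at
`buried_fraction`) and conservation from a bimodal mixture (conserved cores
Beta(10, 2), drifted positions Beta(2, 6)). Each mutation is labelled
pathogenic by a Bernoulli draw at `pathogenic_fraction`; pathogenic
mutations preferentially hit conserved, buried positions (half are
relocated next to a binding site) and take low-similarity substitutions,
benign ones the reverse. The structural score $s_0$ (effect weights over
the seven non-probability features) passes through a logistic link centred
mid-range to give the true pathogenicity probability — the probability is
modelled downstream of the structural evidence rather than entering its own
generation, which keeps the definition non-circular. Evidence files carry
these truths plus Gaussian noise (`noise_sd`); the conservation profile is
min–max re-normalized only when noise pushes it outside $[0,1]$, so at
`noise_sd = 0` the pipeline reproduces the true features exactly (the
end-to-end identity test) and weight calibration recovers the effect
weights to machine precision.

What the generator does *not* emulate: real substitution spectra, codon
structure, 3D geometry, or correlated errors between predictors. Passing
the synthetic suites therefore demonstrates that the pipeline's plumbing,
normalizations and calibration are correct, not that the composite score is
well-calibrated on real proteins — for that, the bundled reference case and
downstream experiments are the evidence.

## Numerical choices and degenerate inputs

* Problem sizes in the tests (400-residue proteins, 20–500 mutations) keep
  the full suite under half a minute while leaving every code path
  exercised; the regression study uses $n = 500$, `noise_sd = 0.05`.
* Duplicate catalog ids merge by summing recurrence; identical duplicate
  evidence rows collapse, conflicting ones error.
* Empty site registries return an infinite-distance sentinel instead of
  erroring, so annotation-poor proteins can still be scored.
* The missing-evidence policy is explicit: `fail` (default), `drop` with a
  logged tally, or `impute` with configured neutral values.
* `row_range` normalization is clamped to $[0,1]$ to absorb rare rows where
  a substitution scores above the self-score in a user-supplied matrix.
* Ranking AUC is the Mann–Whitney rank-sum statistic (ties at 1/2), checked
  against an independent ROC implementation in the tests.

## Limitations

Sequence-window proximity misses spatial adjacency; the between-helices
flag and buried/surface table are only as good as their annotation source;
least-squares calibration against 11 reference rows with 9 parameters
leaves 2 residual degrees of freedom, so fitted weights are descriptive of
the reference, not inferential; and scores carry no significance claims —
the pipeline ranks, it does not test hypotheses.
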