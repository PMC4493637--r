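---
title: "Sequence-based phosphorylation-site prediction: models, encodings and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based phosphorylation-site prediction: models, encodings and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein kinases attach phosphate groups to serine (S), threonine (T) and
tyrosine (Y) residues, and the local sequence context around a residue
carries much of the information about whether a given S/T/Y is a plausible
substrate. phossite builds, evaluates and applies predictors of this kind,
with defaults chosen for plant (specifically rice) phosphoproteome data,
where experimentally verified phospho-serine sites outnumber
phospho-threonine roughly 7:1 and phospho-tyrosine 30:1.

The unit of analysis is the **fragment**: the 25-residue window spanning
offsets −12..+12 around a candidate residue, with the candidate at string
position 13. Windows that overrun a terminus are padded with a reserved
symbol (`-`) that is not an amino acid and not the wildcard `X`; every
encoding skips pad and `X` positions rather than counting them, so the
20-letter feature spaces stay intact for truncated windows. Positions are
1-based in every user-facing table.

```{r, eval = FALSE}
library(phossite)
extract_fragment("MKKSAPTTSLLRS", 4)
#> [1] "---------MKKSAPTTSLLRS--"
```

## Building datasets

`read_fasta()` + `read_sites()` + `build_fragments()` turn a FASTA file and
a site-annotation table into a labeled fragment tibble. Experimentally
verified sites are positives; when the annotation table carries no negative
rows, every unannotated S/T/Y becomes a negative candidate — the standard
construction for this problem, in which "negative" really means "not
observed phosphorylated". Exact duplicate windows within a class are
removed (first occurrence by protein and position wins); windows appearing
in *both* classes are kept and reported, since they are informative label
noise rather than redundancy.

Two optional refinements mirror common practice:

* `filter_inaccessible()` restricts negatives to solvent-buried residues,
  on the argument that a surface-accessible but never-observed site is a
  weaker negative. The accessibility flags come from an external
  surface-accessibility predictor via a plain table; running such a
  predictor is out of scope here.
* `split_fragments()` holds out a per-class fraction (default 1/3) as an
  independent test set and can subsample the training pool to a requested
  (+):(−) ratio. Only the majority pool is ever downsampled; positives are
  never duplicated. The split unit is the site; `by_protein = TRUE` is
  available for users worried about homologous-window leakage between
  train and test.

## The three encodings

**AF** (amino-acid occurrence frequency) is the 20-vector of residue
frequencies in the window, `v_i = c_i / L` with `L` the count of non-pad,
non-`X` positions. It captures compositional bias but no positional or
pairing structure.

**CKSAAP** (composition of k-spaced amino-acid pairs) counts, for each
spacing `k = 0..5` and each ordered pair `(a, b)` of standard amino acids,
the number of position pairs `(i, i + k + 1)` holding `a` then `b`,
normalized by the number of valid position pairs at that spacing:
`N_ab,k / N_total,k`. Pairs touching a pad or `X` are excluded from both
numerator and denominator. Six spacings × 400 ordered pairs give the
2400-dimensional vector. The central residue participates in the counts —
nothing in the construction argues for excluding it, and the `(S, P)`
adjacency it anchors is exactly the kind of signal the encoding exists to
capture. Within each spacing block the 400 values sum to 1 on a pad-free
window (the counts partition the total), a property the test suite checks.

**KNN** encodes each query by its neighbourhood in labeled reference sets.
The distance between two aligned windows is one minus their mean
position-wise similarity under a min-max-normalized BLOSUM62 matrix
(`sim = (B62 − min)/(max − min)` over the 20×20 standard block, so the
worst-scoring pair maps to 0 and the best, W/W, to 1). For each fraction
`f` in 0.1%, 0.2%, 0.5%, 1%, 2%, 5%, 10%, the feature is the ratio

> mean distance to the `k` nearest **negative** references /
> mean distance to the `k` nearest **positive** references,

with `k = max(1, round(f · n_refs))`, rounding half away from zero so the
smallest fractions still use one neighbour. Larger values mean the query
sits closer to the positive class; the direction is fixed package-wide so
saved models are self-consistent. During cross-validation the query is
removed from its own reference class (`exclude_self`), because a zero
self-distance would otherwise leak the label into the feature. A query
duplicated across its entire positive reference pool would produce a zero
denominator; the ratio is then set to a configurable cap (default 1000)
with a warning. Note that under BLOSUM62 an *identical* pair of windows
does **not** have distance zero unless every aligned pair attains the
maximum similarity score — distance zero is an all-tryptophan corner case,
not the generic duplicate case.

Combined schemes concatenate blocks in the fixed order AF, CKSAAP, KNN:
AF-KNN (27), AF-CKSAAP (2420), CKSAAP-KNN (2407) before selection.

## Relief-F selection

The combined encodings are reduced by two-class relief-F: each instance
rewards features that differ toward its nearest misses and penalizes
features that differ toward its nearest hits, with differences normalized
by the feature range and neighbourhoods (default 10 hits and 10 misses)
found under Euclidean distance on range-scaled features. Constant features
receive weight exactly zero. Selection keeps the top-`d` features by
weight — `d` defaults to 27 / 952 / 939 for AF-KNN / AF-CKSAAP /
CKSAAP-KNN — and returns them in the original layout order so the saved
identifier list aligns prediction-time features. Ties are broken toward
earlier layout position, making selection a pure function of the weights.

Selection is fit on training folds only and frozen for held-out folds.
Fitting it once on the full dataset before cross-validation would leak
test labels into the retained set; users who want to mimic that protocol
can select features beforehand with `relieff_weights()`/`select_top()` and
pass the result as an explicit `target_dim` on a pre-reduced matrix.

## Classifiers

Four families share one pipeline (encode → scale → select → fit), all
deterministic given `seed`:

* **SVM** with an RBF kernel (the flagship), on features min-max scaled to
  [0, 1] by training ranges. `cost` defaults to 1. The kernel width
  defaults to the variance-scaled heuristic `gamma = 1/(d · Var(X))`
  rather than the plain `1/d`: CKSAAP features are sparse and small even
  after scaling, and a `1/d` width leaves the kernel nearly flat — on the
  package's own synthetic benchmark it costs roughly 0.13 of MCC, purely
  as an underfit artifact. `gamma = "1/d"` restores the plain reciprocal,
  and `tune = TRUE` runs an inner 3-fold grid search (`cost` in
  0.1/1/10/100, `gamma` across `4^-2..4^2` times the default) scored by
  inner-CV MCC.
* **Random forest**, 100 trees, `mtry = floor(sqrt(d))`, on raw features;
  the score is the positive vote fraction.
* **Decision tree** with Gini splits, on raw features; the score is the
  positive proportion of the assigned leaf.
* **k-nearest-neighbour classifier** (k = 5, scaled features); the score
  is the positive neighbour fraction.

Labels are called by `score >= threshold`, ties positive. The default
threshold is 0 for the signed SVM decision value and 0.5 for the
vote/proportion scores; it is exposed everywhere because the operating
point is a user decision, not a property of the model.

Trained models serialize with everything prediction needs: classifier
state, scheme and parameters, retained feature identifiers, training
scaler ranges, the KNN reference fragments when the scheme needs them, and
a schema version checked at load.

## Evaluation

`compute_metrics()` implements the four confusion-matrix measures
(Sn, Sp, ACC, MCC), with MCC defined as 0 when its denominator vanishes.
`roc_curve()` sweeps every distinct score, collapses ties into single
operating points, anchors at (0,0) and (1,1), and integrates by trapezoid;
this equals the tie-corrected rank-sum probability, and the tests verify
that equivalence against a brute-force pairwise oracle. `cross_validate()`
uses stratified fold assignment (per-fold class counts within one instance
of proportionality — plain random partition can produce degenerate folds
at ratios like 1:0.17), confines every fitted component to the training
folds, and reports pooled (micro-averaged) confusion counts as the
headline with per-fold metrics alongside; pooling is the stabler choice at
small fold sizes, and the per-fold table lets users macro-average if they
prefer. `evaluate_predictor()` refuses any test fragment whose
(protein, position) key occurs in the model's training set. Per-residue
(S/T/Y) breakdowns accompany both.

## The synthetic generator

Real phosphoproteome fragment sets are large, licensed and messy;
`generate_fragments()` exists so every stage of the pipeline is testable
from code alone. Negatives are i.i.d. draws from a background composition
(default uniform over the 20 residues) with the centre drawn from the
S/T/Y distribution (0.85, 0.12, 0.03 — matching the roughly 4220:605:141
abundance of experimentally observed rice phosphosites). Positives add
**positional motifs** (overwrite offset `o` with residue `r` at
probability `p`) and **paired motifs** (rejection sampling that accepts
pair-free candidates with probability `1/enrichment`). The achieved
enrichment is approximate by construction; multipliers below 1 are
rejected, and unreachable pairs (e.g. planted over a background that
never emits the residue) abort with guidance rather than looping.

`preset_generator("strong")` — P at +1 (0.95), R at −3 (0.8), D at +2
(0.6), S-P at spacing 0 (×4), L..K at spacing 2 (×3) — is a deliberate
caricature of a proline-directed kinase signature; `"null"` plants
nothing, making the classes exchangeable. `generate_proteins()` embeds
fragments into random full-length proteins (default 60–120 residues) with
recorded positions, exercising FASTA parsing, window extraction and
padding end to end; lengths below 25 truncate the planted window to test
terminus padding.

What the generator does *not* emulate: realistic proteome composition,
kinase-family structure, homology between fragments, and diffuse
many-weak-feature signal. The last point matters for interpreting
benchmarks: the planted motifs are few, strong and axis-aligned, a regime
in which tree ensembles are close to Bayes-optimal, whereas real
phosphosite signal is spread over many correlated features, where the
RBF-SVM tends to win. On the package's own benchmark
(500+500 fragments, AF-CKSAAP, pooled 10-fold CV) the SVM clears MCC 0.8
comfortably and beats the KNN classifier by a wide margin, but the random
forest and even a single Gini tree edge it out by a few hundredths — a
property of the caricature, not evidence about real data. Passing the
null test (mean CV MCC within ±0.1 of 0 across seeds) shows the pipeline
does not leak labels; it says nothing about real-data accuracy.

## Numerical and design notes

* Problem sizes in the test-suite benchmarks (500+500 fragments for the
  signal benchmark, 150+150 × 5 seeds for the null control, 10 folds) were
  chosen to make stochastic properties stable at comfortable runtimes on a
  single core.
* Neighbour ties everywhere (KNN encoding, relief-F) break by stable sort
  on (distance, reference index); encoding any fragment twice is
  bit-identical; training twice with one seed serializes identically.
* All-pad fragments, empty per-spacing pair totals, zero-range features,
  zero MCC denominators and empty reference pools are each handled
  explicitly (error, zero block with warning, zero weight, 0 by
  convention, error — respectively) rather than propagating NaN.
* Dedup is by exact 25-mer string within a class, the simplest reading of
  "redundant"; sites within 12 residues of a terminus are kept (their
  windows are padded), since discarding them would silently drop terminal
  phosphosites.
* The wildcard `X` absorbs the rare non-standard letters (B, J, O, U, Z,
  `*`) at FASTA read time; `X` positions are excluded from all counts, the
  same treatment as pads, so a selenocysteine never fabricates a pair
  count.

## Limitations

The package predicts from local sequence alone: no structure, no kinase
identity, no conservation. Negatives are unverified by construction, so
reported specificity is relative to "not yet observed", and models trained
on one proteome should not be assumed to transfer. The solvent-
accessibility filter is only as good as the external annotations supplied
to it.
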