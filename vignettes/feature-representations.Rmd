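---
title: "Feature representations, models and evaluation in featkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature representations, models and evaluation in featkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

featkit studies how the encoding of guide-RNA/DNA sequence information
shapes the accuracy and interpretability of gradient-boosted-tree models in
two CRISPR settings: knockout (KO) off-target prediction from paired
gRNA/off-target alignments, and base-editing (BE) efficiency prediction from
single guide sequences. This vignette documents the models and conventions
the package commits to, the tunable parameters that matter, what the
synthetic generators do and do not emulate, and the numerical choices made
where the design was genuinely open.

## Sequence conventions

Sequences are uppercase strings over `{A,C,G,T}` plus the gap symbol `-`
and the ambiguity code `N`. The canonical length is L = 23: a 20-nt
protospacer followed by the 3-nt PAM. Positions are 1-based with position 1
PAM-distal and positions 21–23 the PAM, so the "seed region" — the
PAM-proximal stretch where mismatches are most disruptive to Cas9 binding —
sits at high position indices. Public off-target tables do not state their
orientation explicitly; this convention is a package decision, chosen so
that PAM-proximal effects appear at positions near 20, matching how
positional effects are usually discussed. Encoders derive their
dimensionality from L, so toy lengths (3–5 nt) are first-class in tests,
with the canonical counts recovered at L = 23.

## The eight encodings

Alignment-based encoders consume a (guide, off-target) pair of equal aligned
length; sequence-content encoders consume either member.

* **NPM** — per position, a 4×4 indicator of the (guide base, target base)
  pair: 16L features (368 at L = 23), naming each substitution exactly
  (`pos11_GA` = guide G over target A at position 11). Names are ordered
  guide-base-major, a choice made auditable by the tests.
* **BULGES** — the same grid over the 5-symbol alphabet `{A,C,G,T,-}`:
  25L features (575). A gap in the target fires `(r, -)`, a gap in the
  guide fires `(-, d)`, and `(-,-)` is structurally impossible. The full
  5×5 grid (rather than a single extra channel) was chosen so NPM is an
  exact sub-encoding — on ungapped input the nonzero cells coincide — at the
  cost of two always-zero rows/columns worth of features.
* **LEP** — one integer 0–15 per position, the lexicographic index of the
  pair (AA = 0 … TT = 15). The ordering is a package decision (only
  "unique integer" is required by the construction); `decode_lep()` inverts
  it, which pins the choice down in tests.
* **MM** — binary mismatch indicator per position; its row sum equals the
  Hamming distance, and a gap column counts as a mismatch.
* **8XL** — one-hot of the guide concatenated with one-hot of the target
  (8L = 184).
* **OH** — positional one-hot (4L = 92). For pairs, the two one-hots are
  combined with a bitwise OR at unchanged dimensionality: matched positions
  have block sum 1, mismatched positions block sum 2, so mismatches are
  represented implicitly.
* **OH5C** — one-hot over `{A,C,G,T,X}` (5L = 115) with the X channel
  firing for `-` or `N`, OR-paired like OH. The public performance tables
  that motivated this variant never define it; the 5-channel reading is the
  most parsimonious one consistent with its name and with it being the only
  encoder tolerant of ambiguous bases. This interpretation is flagged as
  such rather than presented as canonical.
* **KMER** — counts of overlapping k-mers (default k = 3, 64 features).
  Because counts per sequence sum to L − k + 1, one level is linearly
  redundant; `kmer_paper_compat = TRUE` drops the lexicographically last
  k-mer (TTT), giving the widely printed 63-feature variant. The default
  emits the full vocabulary. For KO the off-target sequence is encoded (the
  compositional context of the cleavage site); for BE, the guide.

The "-seq-dist" model variants append one explicit integer column,
`distance`, the Hamming distance between the pair members (gap columns count
1). On gapped alignments this is a per-column edit count — a deliberate
extension, since mismatch counts are classically defined on ungapped pairs.

Biophysical descriptors of the guide are available as an optional block:
GC percentage; melting temperature by the Wallace rule
2(#A+#T) + 4(#G+#C) °C, the standard short-oligo approximation (the
upstream feature lists cite no formula); and RNA secondary-structure minimum
free energy parsed from the RNAfold executable when present, with a
documented degradation to an absent column otherwise.

## Preprocessing

KO read counts are heavy-tailed, so regression targets are
y′ = log(y + 1) — natural log by default, base configurable. Activity labels
use a strict count threshold (active iff y > 100); BE labels use the strict
cutoff z < −2.0. Both datasets' labeling boundaries are asserted exactly in
tests (100 → inactive, 101 → active; z = −2.0 → inactive).

With ~97% inactive sites, training uses per-sample class weights
w_active = n_inactive/n, w_inactive = n_active/n, so each class contributes
equal total mass. Only the active-class weight is fixed by the published
formulation; setting w_inactive = n_active/n (rather than 1) is the
symmetric completion — the two differ only by a global scale, which
tree-boosting losses absorb.

## Synthetic data: what it emulates and what it does not

`simulate_ko()` produces paired 23-mers with up to 6 mismatches per guide.
Each site draws a mismatch count m, uniform mismatch positions (positions
13–20 carry a 2× burden multiplier, emulating the seed region), and uniform
substituted bases. The latent mean log count is β₀ − β_mm·burden
(β₀ = 6.0, β_mm = 1.2) and counts are negative binomial (size 2.0) — an
overdispersed model consistent with the ~100-count RMSE magnitudes such
screens report. The mismatch-count sampling weights are calibrated
analytically (hypergeometric seed-overlap × negative-binomial tail
probabilities, a 2×2 linear solve) so the fraction of sites above the
activity threshold matches `prevalence_active` (default 0.03, the ~97%
negative regime). Because the imbalance is produced through the
mismatch-count distribution rather than post-hoc subsampling, distance and
label remain mechanistically linked as in real data.

`simulate_be()` draws guide sequences and builds
z = Σ position effects + Σ 3-mer motif effects + Gaussian noise
(sd 0.6). Default position effects concentrate at PAM-proximal positions
(strongest: A at 20 and 17 negative, i.e. efficient editing), with small
motif terms (GGC −0.35, AAA +0.25). An affine calibration maps the median
to 0 and the `tail_fraction` quantile (default 0.08) to −2, producing the
rare strongly-negative tail; a constant raw score raises a
degenerate-variance error rather than calibrating garbage.

All randomness flows from one integer seed through a per-guide seed stream,
so guide g's records are invariant to `n_guides` and every table is
byte-reproducible.

What the generators do **not** emulate: genomic sequence composition
(uniform base usage), chromatin or epigenetic context, guide-specific assay
efficiency, PAM sequence constraints (the PAM positions are ordinary random
bases), or correlated mismatch placement. Passing tests therefore
demonstrate that the pipeline recovers planted structure of the stated form
— not that it attains any particular accuracy on real screens.

## Models, cross-validation and search

Models are gradient-boosted trees (XGBoost backend), logistic loss for
classification and squared error on the transformed target for regression —
the task formulations fix the targets but not the losses, and these are the
standard choices. Training is single-threaded and seeded, so runs are
exactly reproducible.

Generalization to unseen guides is what matters, so KO evaluation groups by
guide: `leave_one_group_out` (every guide once held out; the package
default) or `leave_k_groups_out` (a seeded permutation of guides chunked
into k contiguous folds — how the 10 sets are formed is unspecified
upstream, so the permutation rule is documented here). BE screens have one
row per guide and use plain 10-fold CV. Fold plans assert zero guide
leakage on every run.

`random_search()` samples hyperparameters from standard tabular-data
ranges — learning rate log-uniform [0.01, 0.3], depth 3–10, 100–1000 trees,
L1/L2 log-uniform [1e−3, 10], subsampling [0.6, 1] — and scores candidates
by mean CV AUPR (classification) or Pearson (regression); the upstream
description names the mechanism but not the ranges or the score, so both
are package decisions. The default `model_spec()` (200 trees, depth 6,
learning rate 0.1) is a deliberately unremarkable middle of that space.

## Evaluation

AUPR uses the average-precision estimator Σ(Rᵢ − Rᵢ₋₁)Pᵢ with tied scores
grouped into one threshold step — conservative under heavy imbalance and
free of the optimism of trapezoidal PR interpolation (the estimator is
otherwise unspecified upstream, so it is pinned here and verified against an
exhaustive-threshold oracle). AUROC uses the Mann–Whitney rank form.
Thresholded metrics default to 0.5 and report precision/F1 = 0 with an
explicit flag when no positive predictions exist.

Regression reports Pearson and Spearman on active-labeled rows only, and
RMSE on the raw count scale after back-transforming exp(y′) − 1 — count-scale
RMSE is the convention the comparable reported magnitudes (~100) imply.
Spearman's subset is ambiguous in the comparable tables; active-only is used
for both correlations, consistently. `tail_error_analysis()` flags the worst
10% absolute errors and reports mean signed error (predicted − true) within
true-z strata split at −4, −2 and 2, which makes regression-to-the-mean
visible as a positive signed error below −2.

## Explainability

`shap_attributions()` returns exact tree-path (TreeSHAP) attributions on the
raw additive margin — log-odds for classification — because that is the scale
on which tree attributions are exact; probability-scale attributions would
not sum to the prediction. Global importance is mean |φ| (the summary-plot
ordering); aggregating local attributions globally has known caveats, which
are surfaced here rather than patched. A per-position roll-up sums mean |φ|
over features sharing a position prefix.

The local-accuracy identity (Σφ + base = margin) is asserted on every
report. Numerical precision: the tree backend stores leaf weights and
accumulates predictions in 32-bit floats, so the identity holds to about
1e−6–1e−5 relative on deep ensembles (hundreds of trees) and to better than
1e−6 on small ones; the default tolerance is 1e−5 and callers can tighten
it where their models allow.

`ale_curve()` implements first-order accumulated local effects: per-bin mean
prediction differences between samples moved to the bin edges, accumulated
and centered to zero sample-weighted mean. Integer-valued features such as
`distance` get one bin per observed value; continuous features get quantile
bins (default 20). ALE rather than partial dependence because the encoded
sequence features are correlated with the distance column by construction.

## Problem sizes and known limitations

The test suite exercises the full pipeline at 20 guides × 500 sites
(knockout, 3 seeds, leave-one-guide-out) and 5,000 guides (base editing,
10-fold) — sizes at which the planted-signal properties (distance lifting
grouped-CV AUPR, SHAP ranking, declining distance ALE, positional encoding
beating k-mers on positional screens) are stable across seeds.

Limitations worth knowing: the package does not enumerate genomic candidate
sites (inputs are assumed already paired and aligned); bulge injection
replaces a base with a gap column at fixed aligned length rather than
re-aligning; OH5C is an interpretation, not a published definition; epigenetic
and chromatin features are out of scope; and headline accuracies on the real
genome-wide screens are not reproducible from this package alone, since they
require the original large-scale datasets.
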