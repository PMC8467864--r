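---
title: "Classifying mechanically stable and unstable protein substructures from sequence"
author: "seqstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mechanically stable and unstable protein substructures from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqstab)
```

## The problem

Single-molecule force spectroscopy on multi-domain proteins resolves them
into cooperative substructures that are either mechanically **stable (S)**
— they refold autonomously and resist force — or **unstable (U)**. For the
*E. coli* Hsp70 chaperone DnaK (638 residues), such experiments assign
four S and three U substructures covering residues 1–603; the disordered
C-terminal tail (604–638) is outside the analysis. `default_dnak_map()`
encodes this assignment; the boundary residue 371, which sits exactly at
the lobe-IIa/linker junction, is assigned to the stable lobe so that the
linker has its documented length of 21 residues.

seqstab asks: can the mechanical class of a residue be predicted from
sequence alone? The package implements the full analysis pipeline —
featurization, unsupervised diagnostics, supervised classification with
leakage control, a negative control, and alignment conservation
statistics — as reusable, tested R functions.

## The model

### Context-dependent features

Each residue is first described by 28 published physico-chemical scales
(`load_scales()`), 19 of them hydropathy/hydrophobicity-type scales
(A1–A19) and 9 context-free descriptors (flexibility, polarity,
refractivity, bulkiness, mutability; A20–A28). A single residue's scale
value carries little information about its substructure; what matters is
the *local chemical context*. The A1–A19 scales are therefore smoothed
with a centered Gaussian moving average over a window of `k` residues
(odd `k`):

* window weights: `w_i ∝ exp(-0.5 ((i - m)/s)^2)` for `i = 0 … k-1`, with
  `m = (k-1)/2` and `s = (k-1)/4`, normalized to sum to 1;
* the center residue receives maximal weight and the window is symmetric;
* `k = 1` is the identity transform (`s` would be 0, so the degenerate
  window is defined as a single unit weight);
* only full windows are emitted: an analyzed region of length `L` yields
  `L - k + 1` feature rows (*edge trimming*), e.g. 573 rows (positions
  16–588) for the 603-residue DnaK region at `k = 31`.

A20–A28 are kept as raw center-residue values. All columns are finally
Z-scored (sample standard deviation) over the retained rows. Because the
28 scales are mutually redundant, a greedy correlation filter drops any
feature whose squared Pearson correlation with an already-retained feature
exceeds 0.95 (earlier scale ids win ties). The "overall correlation"
summary reported by `average_abs_correlation()` is the mean of absolute
off-diagonal Pearson coefficients — the literature leaves open whether
signed `r`, `|r|` or `r²` was averaged, and `|r|` was chosen once as the
most interpretable.

Window sizes of 1, 15 and 31 residues are the reference settings; 31 is
the practical upper limit for DnaK because the shortest substructure (the
21-residue linker) would otherwise vanish entirely under trimming.

### Unsupervised diagnostics

`pca_fit()` (via `stats::prcomp`) plus `informative_projections()` rank
every pair of principal components by the mean fraction of each point's
10 nearest neighbors (Euclidean distance in the 2D projection) sharing its
class label; ties are broken lexicographically, and equal-distance
neighbors by point index. `lda_fit()` computes the closed-form Fisher
discriminant `w = Sw⁻¹(μ_S − μ_U)`; the within-class scatter is
ridge-regularized (`λ = 1e-6 · trace/d`) only when its reciprocal
condition number falls below 1e-10, which can happen after aggressive
correlation filtering. The 1D scores are standardized to unit pooled
within-class variance, so the reported `class_mean_difference` is
comparable across window sizes and invariant to feature rescaling.

### Supervised classification without leakage

`make_split()` holds out the first 40 and last 40 trimmed analyzed
positions (a pure-U and a pure-S block for DnaK). Because a window of
size `k` mixes information across up to `k − 1` neighbors, training
positions within that guard distance of either test block are discarded —
otherwise smoothed features would leak test-region residues into
training. A property test verifies the guard: randomizing the test-block
residues and recomputing features leaves every training row unchanged.

Three classifiers are wrapped behind `model_spec()`/`train_model()`:

* **LR** — ridge-penalized logistic regression (`glmnet`, `alpha = 0`,
  default `lambda = 1e-3`, internal standardization disabled because the
  features are already Z-scored). The ridge keeps the fit defined and
  deterministic on separable data; `lambda` and `maxit` are the tunable
  axes.
* **RF** — `randomForest` with `ntree` (default 500) and `maxnodes` as
  axes, seeded.
* **SVM** — `e1071::svm` with the polynomial kernel
  `(γ⟨x,y⟩ + bias)^power`; sensible default grids are
  `power ∈ {1..5}`, `bias ∈ {0, 0.5, 1, 2}`, `γ ∈ {0.01, 0.1, 1, 10}`.

`forward_feature_selection()` adds, at each step, the feature that
maximizes accuracy on the held-out blocks (ties → earlier feature id),
records the whole trajectory, and returns the best prefix. This matches
the published protocol, in which the held-out blocks also drive
selection; note that it makes the selection step itself an optimistic
estimator, which is why the chance-level control below avoids it.
`grid_optimize()` evaluates every hyperparameter combination exhaustively
(`expand.grid` order, first axis fastest, ties → first).

`evaluate()` reports the 2×2 confusion matrix (rows true U/S), accuracy,
Cohen's kappa `(p_o − p_e)/(1 − p_e)` with `p_e` from the marginals, and
per-class recall/precision/F-measure. `cross_validate()` runs stratified
10-fold CV with a documented balance convention: the per-class remainder
folds are taken from the front for U and the back for S, which makes all
10 fold sizes land on 57–58 for the 573-position DnaK case (a plain
round-robin split would produce one fold of 56). Random-fold CV does not
enforce the window guard — neighboring positions share windows — so its
accuracy is an optimistic companion to the guarded hold-out, not a
replacement. `misclassification_report()` maps errors onto the
substructure map: by class, by domain (NBD = 1–392 including the linker,
SBD = 393–603, configurable) and by `border_distance()`, the distance to
the nearest opposite-class residue.

### The shuffled-scale null

`shuffle_scales()` permutes the 20 values of each scale among amino acids
(never across scales), preserving each scale's value distribution exactly
while destroying the chemical grouping. `shuffle_test()` applies the
published protocol: features are forward-selected with the *real* scales,
the scales are then shuffled, the features rebuilt, and a model restricted
to the same selected subset is retrained and evaluated on the identical
split. The comparison is meaningful precisely because selection was tuned
to the real chemistry; a model free to re-select features from shuffled
scales can often recover, since any injective assignment of values to
amino acids still encodes windowed composition.

### Conservation statistics

For an alignment (`read_alignment()`, aligned FASTA or Clustal),
`wu_kabat()` computes the variability `N·k/n` of each column (`N`
sequences, `k` distinct residues, `n` count of the most common one): 1
for a fully conserved column, up to 400 at depth 20. Gaps are excluded
from `k` and `n` while `N` stays the full depth — the classical
convention; `gap_as_symbol = TRUE` switches to counting the gap as a 21st
symbol. `conserved_positions()` uses the strictest reading of
"conserved": a fully ungapped, invariant column (a configurable gap cap
relaxes this), mapped to reference coordinates through the ungapped
reference row. `identity_matrix()` implements the classical pairwise
rules: both-gap columns are removed, residue-vs-gap counts as a mismatch,
and the denominator is the remaining column count.

## The synthetic generator

`synthetic_spec()`/`generate_labeled_sequence()` produce labeled
sequences with exactly the statistical structure the classifier is
supposed to exploit: within each segment of the layout, residues are
drawn i.i.d. from `p_class = (1 − δ)·base + δ·e_class`. Defaults, chosen
once and kept fixed:

* layout = the DnaK class runs (U 185, S 186, U 21, S 113, U 28, S 70 —
  603 residues, U 234 / S 369);
* `base` = database-average amino-acid frequencies
  (`average_aa_composition()`);
* `e_U` = Ala, `e_S` = Thr — the direction of the compositional contrast
  observed between unstable and stable Hsp70 substructures (Ala-enriched
  U, Thr-enriched S);
* δ is the effect size: 0 makes the classes statistically identical, 1
  makes segments homopolymeric.

`generate_msa()` adds an ungapped family alignment: every non-reference
row mutates each column independently with a given substitution rate.

What the generator deliberately does **not** model: secondary-structure
periodicity, within-class heterogeneity between segments, phylogenetic
correlation between alignment rows, and indels. Passing tests on this
generator therefore demonstrate that the pipeline recovers *compositional*
class signal through windowed features — the mechanism the method claims —
not that it captures every property of real proteins. Two consequences
are worth knowing. First, at δ = 0 the held-out accuracy of a single run
is *not* binomial(80): smoothing correlates the 80 contiguous test
predictions, and single-run accuracies between 0.2 and 0.9 occur at
chance; the chance-level check therefore averages over 20 generator
seeds. Second, because i.i.d. composition makes real and shuffled scales
information-equivalent for a model free to use all features, the shuffle
control is only discriminating in its faithful selected-subset form (see
above).

## Numerical choices and degenerate inputs

* Only odd window sizes are accepted; an even `k` has no center residue.
* Weights sum to 1 within 1e-12; Z-scored columns have mean 0 and sd 1
  within 1e-9; constant columns raise an error naming the column
  (homopolymeric input is rejected rather than silently propagated).
* All coordinates are 1-based inclusive residue positions everywhere.
* Fold assignment, scale shuffling, sequence generation and model
  training are all seeded; reruns with the same configuration are
  byte-identical (`run_pipeline()` stamps outputs with a config hash).
* Problem sizes used by the test-suite experiments: 603-residue DnaK-like
  layouts, 20 generator seeds for the paired shuffle and chance-level
  checks, 10 seeds × windows {1, 15, 31} for the window-effect medians.

## Known limitations

* The packaged scale values were transcribed from the cited literature
  compilations; other compilations differ in rounding for a few entries.
* Real-data reproduction of the published DnaK accuracies (0.925 held
  out, 0.879 CV) additionally requires the UniProt P0A6Y8 sequence (not
  bundled) and depends on the original KNIME defaults; the README
  documents the recipe.
* A constant window size is a crude proxy for local context near borders,
  where windows straddle both classes — exactly where misclassifications
  concentrate.
* The i.i.d. generator cannot exercise chemistry-similarity signal that
  is distinct from composition; a degradation of *re-selected* shuffled
  models is not expected under this generator and is not claimed.
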