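---
title: "Benchmarking metabolite pathway prediction from atom-color features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking metabolite pathway prediction from atom-color features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Metabolic databases link compounds to the pathways they participate in,
but a large share of experimentally identified metabolites have no such
annotation. A practical remedy is supervised prediction: learn, from the
molecular structure of compounds with known annotations, a classifier for
each broad pathway category (amino acid metabolism, lipid metabolism,
nucleotide metabolism, and so on — twelve categories in the default
setup), and apply it to unannotated compounds. `mpathbench` implements the
full benchmark pipeline for this task — feature generation from structure
files, dataset assembly and curation, an information-content filter,
repeated cross-validated model evaluation, and interpretation outputs —
together with a synthetic molecular-graph generator so that every stage is
exercised end-to-end without downloading any database.

## Atom-color features

The structural representation is the *atom color*: a canonical string
encoding one atom together with its bonded neighborhood out to `k` bonds
(the *bond inclusivity*). At `k = 0` a color is just the element plus a
chirality code (`C0`, `O0`, `Cl0`, a chiral carbon `C1`/`C2`), so the
0-bond color counts of a compound are its (non-hydrogen) chemical
formula. At `k = 1` the color also records the sorted multiset of directly
bonded atoms and the connecting bond orders and stereo codes; ethanol's
heavy-atom graph has exactly three 1-bond colors, corresponding to C-C,
C-[C,O] and O-C. The feature matrix concatenates the count vectors for
`k = 0..3`: rows are compounds, columns are every color observed anywhere
in the collection, and a cell is the number of times the color occurs in
the compound.

The canonical serialization is this package's own grammar: the root code
is element plus chirality; each neighbor contributes a parenthesized
substring carrying its recursive color and a `.order.stereo` bond code;
sibling substrings are sorted lexicographically; runs of `n` identical
siblings collapse to a single `n_`-prefixed term. Two design points
matter:

* **Neighborhood semantics.** A `k`-neighborhood is the depth-`k`
  *unfolding tree* of the graph: traversal never revisits an atom already
  on the path from the root, but separate branches may reach the same atom
  (rings are unrolled). Two atoms receive the same color exactly when
  their unfolding trees are isomorphic, respecting elements, chirality,
  bond order and bond stereo. The test suite verifies this equivalence
  against an independent oracle that builds the trees explicitly and
  decides isomorphism by backtracking matching.
* **Hydrogens.** Explicit hydrogens in the input are colored at `k = 0`
  (yielding an `H0` column) and excluded everywhere at `k >= 1`, both as
  roots and as neighbors. The `h_at_k0` switch in `color_config()`
  disables the `H0` column for a strict non-hydrogen formula; chirality
  and bond-stereo contributions can likewise be switched off for
  ablation.

Value-identical feature columns are dropped (keeping the first in column
order and recording the mapping), and compounds with identical feature
vectors are surfaced as duplicate groups: at low inclusivity these are
mostly shared molecular formulas, and the number of duplicate groups
shrinks as `k` grows.

## Dataset assembly

`build_dataset()` runs the assembly cascade and records a provenance
ledger (step, entries before, entries after) that must reconcile exactly:

1. **Label linking.** Compounds link to leaf pathway nodes; each leaf maps
   to a broad category. A compound's label for a category is true iff it
   links to at least one leaf under it; compounds with no category links
   are excluded with a warning listing unknown leaves.
2. **Duplicate merging.** Entries with byte-identical connection tables
   (or, optionally, identical full color vectors) are merged: the
   lexicographically smallest ID is kept, labels are unioned, absorbed IDs
   are recorded. The union rule means merging can never lose a label.
3. **Ambiguity handling.** R-group placeholder atoms (`R`, `R#`, `R1`,
   ...) and repeat-unit markers (`*`) obfuscate part of a structure.
   Their elements are replaced by carbon before coloring — most such
   groups attach through carbon, and the replacement keeps the known
   substructure informative — while the original flags are retained to
   assign compounds to the *ambiguous* subset.
4. **Curation.** A template lists duplicate-feature-vector groups and
   compounds whose metadata mention macromolecule keywords (protein,
   enzyme, peptide, rna, dna — case-insensitive substring over the NAME
   and COMMENT fields); a curator fills in `merge`/`remove`/`keep`
   actions, which are validated all-or-nothing and applied
   computationally. Row removal can create fresh duplicate columns, so
   column de-duplication runs again afterwards.
5. **Information filter.** Entries with fewer than the selected number of
   non-hydrogen atoms are removed (boundary inclusive: threshold 7 keeps
   compounds with at least 7).

## Choosing the atom-count threshold

Compounds with very few heavy atoms carry too little chemical information
to classify reliably. To locate the cutoff, `per_compound_misclassification()`
retrains a random-forest classifier per category many times and records,
for every compound, the fraction of retrainings that misclassify it; the
overall rate is the mean over the categories with both classes present.
The default prediction rule is **out-of-bag**: each repeat trains on the
whole dataset and scores every compound from the trees that did not see it,
so a run with `n_reps` repeats yields `n_reps` observations per compound
and category. A stratified holdout rule (95/5 by default) is available via
`rule = "holdout"`; it is unbiased for any model family but observes each
compound in only ~5% of repeats, which makes the per-compound rates much
noisier at small repeat counts.

`sliding_window_rates()` averages the overall rates over windows of
non-hydrogen atom count (default width 5, both ends inclusive, starts
stepping from 0), and `select_threshold()` returns the start of the first
local minimum — the point where the initial drop in misclassification
ends. Two numerical details:

* **Resolution-aware ties.** Overall rates are quantized at
  `1 / (categories x repeats)`; differences between window means below
  half that resolution are treated as ties, so a "decrease" must exceed
  the measurement resolution to count. With the exact rule (`tol = 0`)
  the comparison is *strictly less than predecessor, at most successor*,
  first occurrence wins.
* **Degenerate series.** A never-decreasing series returns 0; a series
  still strictly decreasing at its end returns the boundary minimum with
  a warning; empty windows are flagged and skipped, never interpolated.

## Models and cross-validation

Three families of binary classifiers are benchmarked per category:
random forest (`ranger`), gradient boosted trees (`xgboost`) and a
multilayer perceptron (`nnet`), the last trained on autoencoder-compressed
features. With 12 categories and two training datasets (full and
non-ambiguous) this enumerates 72 classifier configurations.

* **Folds.** Each CV iteration draws a fresh stratified split (default
  95% train / 5% test, per-class rounding with a floor of one), so folds
  are independent subsamples rather than a partition. When training on
  the full dataset each fold is evaluated on three partitions — the whole
  test set, its ambiguous entries and its non-ambiguous entries; when
  training on the non-ambiguous subset the partitions are the fold's test
  set and the entire ambiguous subset, which is never trained on (it is
  too small) and is enforced as such.
* **Hyperparameters.** The gradient-boosted space follows the benchmark's
  published ranges (alpha 0-2, booster dart/gbtree, eta 0.01-0.5, lambda
  0-2, depth 6-9, minimum split loss 0-2, positive-class scaling 0.5-2,
  subsample 0.2-1). The random-forest and MLP spaces are translated to
  the knobs these backends expose: `ranger` has no cost-complexity
  pruning or log-loss criterion, so its space covers split rule, minimum
  node size, mtry fraction and balanced class weights; the `nnet` MLP
  space covers hidden size, weight decay and training iterations. Tuning
  is seeded random search (default budget 25) scored by MCC on a single
  stratified 80/20 inner split of the training fold; a Bayesian
  optimizer can be slotted in behind the same interface.
* **Autoencoder.** A single-hidden-layer autoencoder (encoder and decoder
  weights trained jointly, full-batch Adam on squared error over
  column-standardized counts, linear activation by default) compresses
  the feature matrix to 10% of its width (`floor(0.10 * F)`); the same
  fitted transform is applied to every subset so full, ambiguous and
  non-ambiguous entries share one encoding. On data of true rank below
  the latent width, its reconstruction approaches the truncated-SVD
  optimum, which the tests verify against `svd()` directly.

## Evaluation and interpretation

Per fold and partition the confusion counts yield accuracy, precision,
recall, F1, the Matthews correlation coefficient and the unit-normalized
MCC `(MCC + 1) / 2`. Metrics with a zero denominator are flagged invalid
and excluded from every aggregate; MCC (defined as 0 when a denominator
factor vanishes) and accuracy are always valid, which is why MCC is the
headline metric for imbalanced categories. Aggregation across categories
weights each (category, fold) score by the category's share of dataset
entries; the weighted standard deviation uses the frequency-weighted
population form `sqrt(sum(w (x - xw)^2) / sum(w))` (the sample-style
correction is a matter of convention; the population form is reported and
documented).

For tree models, per-fold raw importances (impurity for the forest, gain
for boosting) are rescaled by the fold's maximum so every fold's top
feature scores 1.0, and features are summarized by the median across
folds — importance distributions are skewed, so the median is the stabler
location. Feature-presence odds ratios complement importance: among
positive entries for a category, the odds of containing a feature
(count >= 1), divided by the same odds among negatives. Ratios far above 1
mark features associated with pathway involvement, near 0 with exclusion;
division by zero negative odds is reported as infinity (serialized as
`inf` in TSV output).

## The synthetic benchmark

`generate_benchmark()` emulates the structure of a curated metabolite
collection at desk scale so that recovery tests have known ground truth:

* **Molecules** are connected heavy-atom graphs over a C/N/O background
  alphabet: a random spanning tree with degree caps (4 for C/N, 2 for O)
  plus occasional ring-closing edges, sampled bond orders, bond stereo
  and carbon chirality. No valence model is enforced — the pipeline
  consumes graphs, not chemistry.
* **Size spectrum.** Heavy-atom counts follow a clipped lognormal on
  [6, 30] by default — right-skewed with very little mass at small sizes,
  as in real metabolite sets, where only a few percent of compounds fall
  below the information-content threshold.
* **Labels and motifs.** Each of the 12 categories has a target positive
  proportion (defaults interpolate 0.25 down to 0.03, mirroring the
  imbalance of real pathway categories) and a small planted motif whose
  identifying element occurs nowhere else (Cl, F-F, Br, I, S-S, P-O, B,
  Si-C, Se, As-O, Sn-C, W-O), so the signal is recoverable from atom
  colors at any bond inclusivity. Compounds at or above the signal size
  threshold contain category `c`'s motif exactly when their label for `c`
  is positive; compounds below the threshold keep labels drawn
  independently of their structure; a label-noise rate flips labels after
  assignment. At `label_noise_rate = 0.5` labels are independent of
  structure everywhere — the null benchmark.
* **Ambiguity and curation hooks.** Molecules carry R-group or
  repeat-unit markers with configurable probabilities (defaults give
  ~6% ambiguous entries); the generator can also emit duplicated
  molfiles under fresh IDs with an extra label (exercising merge-and-
  union) and metadata rows containing macromolecule keywords (exercising
  the curation template).

What passing tests on this generator do **not** show: real molfiles have
valence-consistent structures, charges, isotopes and coordinate blocks
with far richer element usage; real pathway labels are correlated across
categories and only partially predictable from any substructure; and the
real collection is five times larger with features in the ten-thousands.
Results at desk scale validate the machinery (parsing, canonicalization,
bookkeeping, statistics), not the attainable real-data performance.

## Problem sizes used by the test suite

The shipped tests run the canonicalizer oracle on 500 random graphs of up
to 12 atoms at every bond inclusivity; the threshold-recovery study on 20
seeded benchmarks of 1,000 compounds with 20 misclassification repeats
each (0-bond features, which already identify every planted motif); the
null-limit check on 200 CV folds; and the importance-recovery study on 10
seeded runs of 250 compounds across all 12 categories. These sizes were
chosen so the full suite completes comfortably on a single CPU while
keeping each statistical check adequately powered.

## Known limitations

* The canonical color strings are structurally equivalent to, but not
  byte-identical with, other atom-coloring implementations; column names
  are stable only within this package.
* The out-of-bag misclassification rule is specific to the random-forest
  family; other families fall back to the holdout rule.
* The MLP consumes encoded features only; training it on raw
  ten-thousand-column count matrices is out of scope.
* Only V2000 connection tables are parsed; V3000, SMILES, charges,
  isotopes and 3-D geometry are ignored by design.
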