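---
title: "Selecting small descriptor sets for QSAR classification"
author: "qsarselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting small descriptor sets for QSAR classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarselect)
```

## The problem

Screening campaigns in early drug discovery routinely produce data of an
awkward shape: a modest number of assayed molecules (tens to low hundreds)
described by a very wide table of computed molecular descriptors
(PaDEL/ChemDes-style tables run to ~1,500 columns: E-state, autocorrelation,
Burden eigenvalue, topological and constitutional families, among others).
Two classification questions recur for such tables: is a compound toxic to
the assay cell line, and does it produce the phenotype of interest — here,
lengthening the period of the circadian bioluminescence rhythm, the
phenotype expected of cryptochrome (CRY1) stabilizers. With p >> n,
classifiers fit on the full table overfit badly, so the scientific object of
interest is a *small* descriptor set (on the order of 10) that still
predicts the label, and that medicinal chemists can interpret and reuse to
triage large virtual libraries.

`qsarselect` implements that selection pipeline end to end: cleaning,
class weighting, recursive feature elimination (RFE), grid-tuned replicated
cross-validation over a cardinality sweep, greedy backward pruning, and a
high-replication final validation. A synthetic descriptor generator with
recorded ground truth makes every stage testable without any proprietary
screen data.

## Data model

The central container is `DescriptorSet`, an S4 class extending
`SummarizedExperiment`: the assay holds descriptors in rows and molecules
in columns (Bioconductor convention), `descriptorMatrix()` returns the
molecules-by-descriptors orientation the learners consume, and binary class
labels live in `colData()$class` with the positive-class name in the object
metadata. Reading (`readDescriptorTable`) accepts the PaDEL dialect —
comma-separated, header row, identifier column first — plus TSV via the
`sep` argument; empty cells and any case spelling of NaN/Inf survive the
load as non-finite entries so that cleaning is explicit and auditable
rather than silent.

## Preprocessing

Two feature-wise cleaning steps run before any learning:

* `dropNonfiniteFeatures()` removes every descriptor containing a
  non-finite value. Removal, not imputation: descriptors are deterministic
  functions of structure, and a failed computation carries no usable
  signal.
* `dropConstantFeatures()` removes descriptors repeating one value across
  all molecules. Constancy is exact equality — again because descriptors
  are computations, not noisy measurements, no tolerance is appropriate.
  Real screen-scale tables lose a large block here (several hundred of
  ~1,500 columns).

Class imbalance (roughly one third positives in both motivating screens)
is handled by inverse-class-size weights

$$w_{+} = \frac{n}{2\,n_{+}}, \qquad w_{-} = \frac{n}{2\,n_{-}},$$

so each class carries exactly half of the training mass
($n_{+}w_{+} = n_{-}w_{-} = n/2$). For a 56/115 split these evaluate to
1.53 and 0.74 (two decimals); for 27/63, 1.67 and 0.71. Training always
uses full precision; rounding is for reporting only. The weights enter all
four learner families uniformly as per-sample training weights; the
*evaluation* metric stays plain unweighted accuracy, reported in percent.

## Estimator families and backends

Four tree-based families serve both as RFE estimators and as final
classifiers: a single CART decision tree (`rpart`), a random forest and an
extremely-randomized-trees forest (`ranger`, the latter via
`splitrule = "extratrees"` without bootstrap), and gradient-boosted trees
(`xgboost`, tree booster). Hyperparameters use the conventional QSAR
naming (`max_depth`, `min_samples_leaf`, `n_estimators`, ...) and are
translated internally. Two grid axes are not expressible in these
backends and are deliberately absent: `rpart` evaluates every feature at
every split, so the single-tree grid has no per-split feature subsampling
(`max_features`), and `ranger` exposes a single node-size control, carried
as `min_samples_leaf` with no independent `min_samples_split`. All other
axes follow the full-scale protocol exactly (`defaultGrid()`): depth 1–10
plus unlimited for the tree, depth 1–6 plus unlimited with 100/200 trees
for the forests, and learning rate 0.01/0.1, depth 3/5/7/10, child weight
1/3/5, row/column subsampling 0.5/0.7 and 100/200 rounds for boosting.

Determinism is a contract, not an accident: every fit runs under the
estimator's seed (some backends draw from the R RNG, e.g. for weighted
bootstrap tie-breaks and prediction-time vote ties, so the fit and the
forest prediction both receive explicit seeds), and every CV replication
$r$ derives its fold shuffle and learner seed as `baseSeed + r`.

## Feature selection

`rankFeaturesRFE()` is importance-ranked backward elimination: train on
the surviving features, rank by the learner's internal split-gain
(impurity-decrease) importance — the one importance all four families
expose natively — and discard the least important feature; repeat until
all features are ordered. One feature per round (the canonical step) makes
the resulting sets fully nested, so a single ranking yields the whole
cardinality sweep: `cardinalitySweep()` slices out the k last-surviving
features for each k in 2–20 (19 candidate sets per family). Importance
ties eliminate the lexicographically last name, which keeps rankings
reproducible and auditable.

For very wide tables the ranking admits a coarse-to-fine speedup
(`step`/`fineBelow` in `rankFeaturesRFE()`, `rfeStep` in `runConfig()`):
several features may be dropped per round while the surviving set is far
above the sweep range, reverting to one-per-round once it reaches twice
the maximum sweep cardinality. Within a round, dropped features are
ordered by ascending importance, so the elimination order remains a
total order and every cardinality slice stays nested; only the orderings
that the sweep never examines are coarsened.

## Evaluation, selection and pruning

`repeatedCV()` runs replicated stratified 10-fold CV. Stratification
matters at these sizes: with 27 positives among 90 molecules an
unstratified 10-fold split can produce positive-free folds. Fold labels
are dealt per class as evenly as possible (per-fold class proportions
deviate from global by at most one molecule) and reshuffled per
replication. `gridSearchTune()` evaluates the full Cartesian product under
shared fold seeds and breaks accuracy ties toward the smaller model
(shallower, then fewer trees, then grid order).

The (family, cardinality) winner of the sweep is chosen by maximum mean
accuracy *with a parsimony tolerance* (default 0.5 percentage points):
among all cells within the tolerance of the maximum, the smallest
cardinality wins. This encodes as an explicit rule the judgment calls a
practitioner makes when a 14-feature set sits within a fraction of a
percent of a 19-feature one, or a boosted model edges out a forest with
one feature fewer; the override can never select a set more than the
tolerance below the maximum.

`backwardPrune()` then interrogates the chosen set: at each step every
single-feature deletion is evaluated by replicated CV — all candidates
under identical replication seeds, so comparisons are paired — and the
deletion with the highest mean accuracy is made. Ties prune the smaller
standard deviation, then the lexicographically first name. Pruning
continues until the mean has declined for `extraSteps` consecutive steps
(default 2), so the trace shows the decline past the peak rather than
stopping blind at it, and the returned set is the argmax over all steps. When depth
was left unlimited by the sweep tune, `retune = "max_depth"` re-runs a 1-D
depth sweep on the surviving set after each deletion; retuning applies to
the winning reduced set rather than to every candidate, which keeps the
step cost linear in the set size.

`finalValidation()` re-runs the CV at high replication (10,000 in the
full-scale protocol) and summarizes the accuracy distribution by a
moment-fitted normal ($\mu$ = sample mean, $\sigma$ = sample SD) plus a
histogram — the accuracy distributions at these sample sizes are
approximately normal, and the fit makes that checkable.

## The synthetic generator

`generateDataset()` draws tables with the statistical structure the
pipeline assumes, with every planted fact recorded in a ground-truth
object (`recoveryScore()` measures how much of it a selected set found):

* exact class counts: `round(positiveFraction * n)` positives — 56 of 171
  at 33%, 27 of 90 at 30%;
* a constant block (defaults 334 of 1538, matching the scale seen in real
  PaDEL tables);
* a small informative set driving the boundary. The default
  `additive_threshold` labels molecules by a quantile cut on the sum of
  the informative features — learnable by shallow trees, like the
  depth-limited winners real screens produce. `axis_threshold` plants a
  single separable feature (a stump suffices); `xor_pair` plants a parity
  structure no stump can learn, used to exercise tuning;
* redundant features: informative sources plus Gaussian jitter calibrated
  so the copy–source correlation equals `blockCorrelation` (default 0.9),
  emulating the strongly correlated descriptor families of real tables;
* noise: independent standard normals, with ~15% count-like integer
  columns echoing the mixed continuous/count marginals of PaDEL families;
* label noise as paired positive/negative swaps
  (k = `round(labelNoise * n / 2)` each way), so the printed class counts
  stay exact while ~`labelNoise` of molecules are mislabeled.

What the generator does *not* emulate: real descriptor marginals
(heavy-tailed, lattice-valued), the dense correlation structure across
whole descriptor families, or any actual chemistry. Passing tests
therefore demonstrate that the machinery ranks, tunes, prunes and
validates correctly on data of the assumed structure — not that any
particular descriptor list generalizes to a real screen.

## The drug-likeness pre-filter

`applyDruglikenessFilter()` reproduces the seven-rule library screen
applied before docking: eliminate molecules with >7 H-bond donors, >12
acceptors, >600 Da, logP > 7, >8 rotatable bonds, fewer than 3 aromatic
rings, or fewer than 4 rings total. All rules are strict inequalities —
values exactly at a threshold pass — and the ring rules are elimination
conditions like the other five (a molecule needs ≥3 aromatic and ≥4 total
rings to survive). Each discarded molecule's report lists every violated
rule; molecules with missing or invalid properties are flagged, never
silently kept.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the pipeline at desk
scale, chosen so a complete run takes minutes on one core while
preserving the protocol's shape: synthetic tables of 171 × 300 (60
constant, 8 informative, 20 redundant, 5% label noise), 2–20 cardinality
sweeps with coarse-to-fine ranking (`rfeStep = 5`), 2 CV replications per
sweep cell, 20–100 final-validation replications, and 10 generator seeds
for recovery estimates. The
replication counts scale the *precision* of accuracy estimates, not the
logic being exercised; full-scale runs (100 sweep replications, 10,000
final replications, complete grids via `tune = "full"`) use the same code
paths. Worth knowing:

* all accuracy bookkeeping is in percent (0–100), matching the field's
  reporting convention;
* cleaned counts are reported as computed (no attempt is made to
  reproduce any historical off-by-one in discarded-feature arithmetic);
* degenerate inputs fail fast and loudly: duplicate identifiers, missing
  labels, more than two classes, all-constant tables, empty grids,
  cardinality ranges wider than the cleaned feature space;
* a CV replication whose training folds lose a class (possible only
  unstratified) is flagged and re-drawn with a shifted seed.

## Limitations

Accuracy is the only evaluation metric, mirroring the protocol the
package reproduces; no ROC/PR or calibration analysis is provided. RFE
rankings from a single tree are high-variance at p >> n — the forest and
boosting families rank more stably, at higher cost. The parsimony rule
and the pruning stopping rule are explicit but simple; neither performs
nested cross-validation, so reported accuracies are model-selection-biased
upward, as in the original protocol. Descriptor computation itself
(structures to descriptors) is out of scope: the package consumes tables.
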