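---
title: "Associative classification of CT texture features: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associative classification of CT texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahmine)
```

`sahmine` screens grayscale CT-like slices for subarachnoid hemorrhage by
coupling second-order texture statistics with classification-association
rule mining. This vignette explains the model at each stage, the
parameters that matter, the numerical conventions, what the synthetic
generators do and do not emulate, and the design decisions taken where
the method leaves room.

## 1. The cooccurrence model of texture

A hemorrhage region differs from healthy tissue less in absolute
brightness than in *spatial* gray-level structure: irregular edges, dark
surfaces, rough texture, uneven distribution. The gray-level cooccurrence
matrix captures exactly that: for a quantized image and an offset given
by distance `d` and angle θ, entry `(i, j)` counts how often gray levels
`i` and `j` occur at that displacement.

Two counting conventions are in circulation, and they disagree on the
diagonal. The convention used here counts each **unordered** adjacent
pair once and mirrors it off-diagonal: a single contiguous `(1, 1)` pair
yields `M(1,1) = 1`, and two contiguous `(1, 2)` pairs yield
`M(1,2) = M(2,1) = 2`. The conventional add-transpose ("ordered
symmetric") matrix would instead give `M(1,1) = 2` for the same image.
Both produce symmetric matrices and identical *off*-diagonal structure;
contrast-type features are unaffected, energy/entropy shift slightly.
The package defaults to the unordered convention and exposes
`counting = "ordered-symmetric"` in `glcm_params()` for interoperability
with other GLCM implementations.

Offsets are defined in `(row, col)` coordinates with row 0 at the top:
0° → `(0, d)`, 45° → `(−d, d)`, 90° → `(−d, 0)`, 135° → `(−d, −d)`.

### Features

With `p(i, j)` the normalized matrix, marginals `p_i`, `p_j`, marginal
means μ and standard deviations σ:

| feature | formula | reads as |
|---|---|---|
| energy | Σ p² | uniformity; 1 for a single-valued texture |
| contrast | Σ (i−j)² p | local gray-level variation |
| entropy | −Σ p log₂ p | randomness; 0·log 0 ≡ 0 |
| mean | Σ i p_i | marginal gray-level mean |
| local stability | Σ p / (1 + (i−j)²) | inverse difference moment (homogeneity) |
| correlation | Σ (i−μᵢ)(j−μⱼ) p / (σᵢσⱼ) | linear row–column dependence |

"Mean" and "local stability" are the standard Haralick quantities closest
to the names used in the screening literature this pipeline follows; no
formulas are fixed there, so the closest canonical definitions were
adopted. Correlation is undefined when a marginal variance is zero
(constant quantized image); `compute_features()` errors by default and
can flag the value as 0 (`degenerate_correlation = "zero"`), which is
what batch extraction uses so near-constant slices flow through.

### Parameters

* `levels` (default 16): quantization target. Cost of the GLCM grows as
  L²; 16 levels keep the six features stable on 32×32 thumbnails while
  remaining cheap.
* `distance` (default 1): nearest-neighbor texture; larger `d` probes
  coarser structure but discards border pixels.
* `angles` (default all four): features are averaged across angles as a
  rotation-robust summary.
* Quantization is uniform over the *observed* integer range
  (`floor((v − min)·L / (max − min + 1))`), so features are invariant to
  global gray-level shifts; a constant image maps to level 0.

## 2. From features to transactions

Records follow the schema `PN, PD, H..M, Class`: a record id, the
clinical prediagnosis bit, six feature bits and the confirmed outcome.
Each feature maps positionally onto `H..M`; the bit is 1 iff the value
exceeds its threshold, with ties mapping to 0. Thresholds are either
explicit or per-feature training medians (`"median-split"`, the default
— it guarantees balanced bits whenever a feature has signal). A constant
feature under median-split binarizes to all zeros with a warning rather
than an error, because a degenerate feature should not abort a cohort
run.

The package also implements the screening rule used on this schema — a
record screens positive iff `PD = 1` and at least two of `K, L, M` are 1
— and ships a ten-record reference fragment (`table1_fixture()`). On
that fragment the rule agrees with the confirmed outcome on 9 of 10
records; the one deviation (PN 67) is a confirmed positive the rule
misses, which is precisely the argument for mining rules from data
rather than fixing them by hand.

## 3. The miners and their contract

All miners share one contract: return exactly the itemsets whose support
fraction is ≥ `min_sup`, with exact integer counts. `brute_force_mine()`
(exhaustive enumeration, refused beyond 20 items) is the oracle; Apriori,
DHP, Partition and FP-growth are tested to be byte-identical to it on
randomized databases, including their serialized JSON.

Numerical conventions:

* Support thresholds are compared in the count domain
  (`count ≥ min_sup · n − 1e-9`); the epsilon absorbs only float
  representation error, never a whole count — boundary cases are common
  at these database sizes.
* Canonical item order is locale-independent lexicographic (radix sort);
  equal-support items in the FP ordering fall back to it. Both choices
  exist purely to make output deterministic.
* DHP's hash (unspecified in the classical description) is a stable
  polynomial over canonical item indices modulo the bucket count
  (default 1024). Bucket totals over-count true support, so pruning can
  only discard infrequent candidates.
* Partition's per-segment threshold is `ceil(min_sup · segment_size)`
  occurrences — rounding up preserves the guarantee that every globally
  frequent itemset is locally frequent somewhere.
* FP-growth recursion depth is bounded by the longest transaction (eight
  items in the screening schema), far below R's call-stack limits for
  any realistic attribute table.

## 4. NCFP-growth: the dual threshold

NCFP-growth filters items by a second, support-independent criterion
while the pattern tree is built: each item carries an interest-degree
weight, and only items with weight ≥ `min_up` (and support ≥ `min_sup`)
enter table L, the tree, and therefore any mined itemset or rule. Three
properties pin the semantics down, and all three are tested:

* **Reduction**: `min_up = 0` reproduces FP-growth exactly, tree bytes
  included.
* **Oracle**: the output equals exhaustive mining restricted to
  weight-passing items.
* **Monotone pruning**: raising `min_up` never adds an itemset, a rule,
  or a tree node.

The interest weight itself is deliberately open: no single measure is
canonical, so weights are user-supplied per item (default 1.0). As a
classification-oriented convenience, `class_lift_weights()` sets each
item's weight to its best lift toward any class,
`max_c conf(item → c) / fraction(c)`: class-irrelevant items sit near 1,
predictive items above it, so a `min_up` slightly above 1 (e.g. 1.2)
suppresses exactly the items that cannot help a classifier. Weight
filtering applies to *items*, not itemsets — an itemset passes iff every
member passes — matching the tree-construction step where each
transaction is filtered before insertion. Table L is kept in descending
support order (the standard FP-growth header order; descending and
ascending orders yield the same mined set, but descending maximizes
prefix sharing and hence tree compression).

## 5. The classifier

Rule generation follows the two-step scheme: from every frequent itemset
T and nonempty proper subset S, emit `S → (T − S)` iff
`σ(T)/σ(S) ≥ min_conf`. Classification-association rules (CARs) are the
subset with a single `Class=` consequent and a class-free antecedent;
they are extracted directly from the frequent set in linear time (each
itemset containing exactly one class item contributes at most one CAR),
which is tested equivalent to filtering the full rule set.

No construction method for the final rule list is canonical, so the
package adopts the CBA-M1-style reading, the standard one for
"classifier size" counts: rank CARs by confidence desc, support desc,
antecedent size asc (generality), canonical key; walk the list keeping a
rule iff it correctly classifies at least one still-uncovered record,
covering every record its antecedent matches; default to the majority
class of uncovered records (global majority when none remain, ties
canonical). Coverage pruning provably never increases training error of
the first-match list, and that invariant is tested on noisy planted
databases.

Accuracy is micro accuracy (correct/total) per held-out fold, averaged
over stratified folds; stratification errors out when any class has
fewer records than folds, rather than silently producing empty strata.
Experimental defaults mirror the screening protocol: `min_sup = 0.01`,
`min_conf = 0.50`, 10 folds. When NCFP weights are data-derived, pass
`reweight = class_lift_weights` to `cross_validate()` so weights are
recomputed per training fold; computing them once on the full data would
leak held-out labels into the weight filter.

## 6. What the generators emulate — and what they do not

Because no clinical image database ships with the package, two seeded
generators define the study conditions; they are first-class tested code.

**Textured images** (`texture_spec()`): the normal class is smoothed
Gaussian noise around a base intensity (base 120, noise sd 12, box-blur
radius 1 on 32×32 slices); the abnormal class adds 3 random-walk-dilated
blobs (60 steps, one 3×3 dilation) that are darker by `blob_contrast`
(default 80) and internally rougher (sd = contrast/4). Random walks
rather than discs give the irregular edges and rough interior texture a
hemorrhage shows; scaling the in-blob roughness with the contrast makes
`blob_contrast = 0` an exact null — the two classes then differ only in
label. The simulated prediagnosis bit PD is derived from the image
itself (contrast above the cohort median, flipped with probability 0.1),
not from the true label: a radiologist reads the image, not the answer
key, and this keeps PD uninformative exactly when the image signal is
absent. What is *not* emulated: anatomy, scanner physics, slice
geometry, partial-volume effects, or lesion segmentation — passing tests
show the pipeline recovers texture signal it is pointed at, not that it
reads real CT.

**Planted-rule transactions** (`planted_rule_spec()`): each rule
`A → Class=c` with requested support s and confidence q gets a block of
`round(n·s/q)` transactions carrying A, each labeled c with probability
q; leftover transactions get uniform classes; independent noise items
appear anywhere with the noise rate. Empirical support lands within
binomial error of the request, and confidence-1 rules are realized
exactly. One subtlety is worth recording: at planted confidence 1.0 the
planted rules *deterministically* outrank every noise-contaminated rule
(equal confidence falls to support, where planted antecedents dominate
by an order of magnitude), but at confidence ~0.95 a noise-augmented
antecedent can reach empirical confidence 1.0 on its small subsample and
legitimately rank first. Rule-recovery guarantees should therefore be
claimed only in the exact-confidence regime, and that is the regime the
tests exercise.

## 7. Problem sizes and reproducibility

All verification batches are sized for exactness rather than scale, a
deliberate choice: randomized miner-equivalence suites use 100 databases
of up to 12 items and 64 transactions (small enough for the exhaustive
oracle, large enough to hit every join/prune/conditional-tree path);
feature formulas are checked on 100 random probability matrices against
an independent double-loop evaluation; the planted-rule regime uses
n = 500 with two confidence-1.0 rules; the image pipeline runs 100
32×32 slices through 10-fold CV. Every stochastic component takes an
explicit seed and restores the caller's RNG state, so identical
configurations reproduce identical artifacts byte for byte.

## 8. Known limitations

* The interest weight is a modeling input; `class_lift_weights()` is one
  sensible choice, not a learned quantity.
* The unordered counting convention and the "mean"/"local stability"
  readings are documented interpretations of under-specified names;
  both alternatives are either provided (`ordered-symmetric`) or a
  one-line change.
* Median-split binarization discards within-feature ordering beyond one
  bit; informative multi-threshold discretizations are out of scope.
* Accuracy on the synthetic cohort says nothing about clinical
  performance; the generators contain no anatomy and the pipeline does
  no segmentation.
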