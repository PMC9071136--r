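---
title: "Similarity fusion for shared-target prediction: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity fusion for shared-target prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pairtarget` casts ligand-based target prediction as binary classification
of *compound pairs*. The working hypothesis is that two molecules sharing
at least one protein target lie close together in a high-dimensional
structural space that no single similarity score spans on its own. Each
pair is therefore described by three complementary blocks:

1. **Seven fingerprint Tanimoto scores.** Circular (Morgan/ECFP-like,
   radius 2), feature-circular (FeatMorgan/FCFP-like, radius 2,
   pharmacophoric atom invariants), atom-pair, linear-path
   (Daylight-like), topological-torsion, layered substructure paths, and
   the 166-key structural key set. All seven are kept because their
   rankings of the same pairs disagree substantially (the
   `cat_concordance()` diagnostic quantifies this); each encodes a
   different facet of structure.
2. **Maximum common substructure (MCS) statistics.** The atom count of
   the largest common connected substructure, its Tanimoto form
   `|MCS|/(n_A + n_B − |MCS|)`, and the overlap coefficient
   `|MCS|/min(n_A, n_B)`, which is informative when the two molecules
   differ strongly in size. `ts_mcs ≤ oc` always.
3. **Per-molecule descriptor vectors**, concatenated for both molecules in
   canonical (lexicographic) id order, covering the five classical
   categories: constitutional, topological, geometrical, electronic and
   hybrid.

With `d` descriptors per molecule the pair vector has length `7 + 3 + 2d`;
the classical 225-descriptor registry yields 460 predictors. The response
is `Match` when the annotated target sets intersect. Collapsing
multi-target sharing to a binary response keeps the task well-posed on
sparse annotation data; per-target prediction is deliberately out of
scope.

## Leakage control: compound-disjoint splits

Pairing amplifies leakage: if a molecule appears in both train and test
pairs, its per-molecule descriptor block is memorised and test performance
becomes meaninglessly optimistic. The protocol therefore splits the
*compound library* 80/20 first (stratified by structural superclass, with
largest-remainder rounding so the global test share is exact) and
enumerates pairs within each side only. Cross-side pairs are discarded
entirely — the accounting identity
`C(N,2) = C(n_train,2) + C(n_test,2) + n_train·n_test` is asserted in the
tests. On the classical 1,410-compound library this yields exactly
1,128/282 compounds and 635,628/39,621 pairs. The split is repeated
`K = 5` times with consecutive seeds; every downstream result is reported
per split or aggregated over the five.

Stratification is *enforced* here (per-stratum random allocation). The
reference protocol is ambiguous between enforcing and merely monitoring
class balance; enforcement is the stricter reading and is deterministic
given the seed.

## Learners and their weighting

* **Regularized logistic regression (L1R/L2R)** on standardized
  predictors (centering/scaling learned on the training side only and
  stored with the model). Class weights are prevalence-derived — positive
  class `1 − p`, negative `p`, i.e. 0.97/0.03 at the classical imbalance.
  The cost `C` comes from a scale heuristic: a class-balanced subsample is
  drawn, standardized, and `C = 1/mean(‖x‖²)`; the penalty is
  `λ = 1/(nC)`. This reimplements the intent of the classical heuristic
  for linear classifiers rather than porting it bit-for-bit.
* **Gaussian naive Bayes**, unweighted, with class-conditional standard
  deviations floored at 1e-6 so near-constant features cannot produce
  degenerate densities.
* **Random forest**: probability forest with the positive-class weight
  applied to the splitting rule. Hyperparameters are tuned by 10 random
  draws from `ntree ∈ {50,…,300}`, `nodesize ∈ [20,50]`,
  `mtry ∈ [15,30]`, `classwt ∈ [300,3000]`, each scored by stratified
  5-fold CV mean MCC; ties resolve to fewer trees, then larger nodesize.
  MCC is the selection metric because it is the most balanced single
  summary of a confusion matrix under a 0.03 class ratio. The tuning
  range for `ntree` has no stated lower bound in the reference protocol;
  we draw from 50 upwards in steps of 50. The forest backend is `ranger`
  with a single thread and a fixed seed, so tuning tables and predictions
  are bit-reproducible.

Probabilities are used raw (no recalibration): the screening protocol
thresholds them at 0.5, and recalibration would silently move that
threshold.

Note the two weighting schemes are intentionally different
parameterizations: logistic regression uses the 0.97/0.03 observation
weights while the forest searches a 300–3000 splitting-rule weight. They
are kept as stated per algorithm rather than unified.

## Evaluation

`compute_metrics()` reports the full imbalance-aware suite (MCC, F1, PPV,
TPR/FPR/TNR/FNR, balanced accuracy, kappa, MMCE, accuracy) at a strict
`probability > threshold` rule, plus ROC and precision–recall curves swept
over the probability ranking with trapezoidal AUCs. Zero-denominator
cases (degenerate confusion rows) are defined as 0 and flagged;
single-class label vectors leave the rank metrics `NA` rather than
fabricating a curve. The implementation is checked in the tests against a
brute-force O(n²) ROC construction and an independent AUC implementation.

## Screening protocol

Query (e.g. natural-compound) libraries are paired against the full
reference (drug) library with exactly the training-time predictors and
projected through the training column mask. Near-duplicate pairs
(fingerprint Tanimoto > 0.9 — strict inequality, circular fingerprint by
default since it is the most identity-specific of the seven) are flagged
and excluded from hit calling: such pairs are almost always the same
molecule present in both libraries. A pair is a hit when at least 3 of
the 5 split models assign Match probability strictly above 0.5. Raising
either dial can only shrink the hit set; this monotonicity is asserted on
every screen in the test suite. `rank_vs_single_fingerprint()` contrasts
the consensus ranking with a single fingerprint's ranking — the pattern of
interest is the pair called by the models but ranked low by the
fingerprint, which a single-score screen would miss.

## The synthetic study design

`generate_library()` builds scaffold families: each family is one of 16
valid ring-system templates plus a family-specific core substituent, and
members differ only in randomized peripheral decorations (2 substituent
edits by default). Members share the family's targets; family pairs
additionally share a target with probability `p`. The default
configuration — 30 families × 5 compounds, `p = 0.003` — gives 11,175
pairs at an expected Match prevalence

```
[F·C(m,2) + p·C(F,2)·m²] / C(Fm,2) ≈ 0.0298,
```

matching the ~0.03 class ratio of the classical drug dataset. These sizes
are the package's desk-scale study conditions: large enough that the
0.03 imbalance leaves dozens of positives in a held-out fold, small
enough that the full five-split, four-classifier protocol runs in
minutes. `generate_screen_library()` adds query compounds (a stated
fraction decorated from reference-family scaffolds as planted positives,
the rest from query-only cores as negatives) plus a few exact copies of
reference compounds to exercise the near-duplicate removal path.

What the generator emulates: scaffold-family structure, strong
within-family structural similarity, rare cross-family target sharing,
and the class imbalance. What it does not emulate: the property
distributions of real medicinal chemistry (molecular weight spread,
stereochemistry, charge states, tautomers), annotation noise (real target
maps contain errors and systematic under-annotation), and the
heterogeneous provenance of real libraries. Passing the synthetic
acceptance checks therefore demonstrates that the pipeline recovers a
planted structure–activity signal under realistic imbalance — not that
the learned models transfer to any particular real library.

## Numerical and design choices

* **Canonicalization** is OpenBabel canonical SMILES; idempotence is
  asserted per fixture molecule. Multi-fragment records keep the largest
  organic fragment (logged); input ids are authoritative and no
  structure-based merging happens at load time.
* **Fingerprint parameters are pinned** (circular radius 2; 4096/2048/1024
  bit spaces per kind; 166-key set fixed) because reproducibility
  requires pinning even where the reference protocol relied on tool
  defaults. Empty∩empty Tanimoto is 0 with a warning, never NaN.
* **MCS** uses element + bond-order compatibility (aromatic bonds carry
  their own order code), connected induced common subgraphs, and a 5 s
  per-pair time budget; pairs that exhaust it are excluded with a count.
  No fuzzy atom/bond mismatching is attempted.
* **Descriptor registry** is a versioned artifact (v1.0, d = 54 across
  the five categories); the classical 225-descriptor list is not
  recoverable from its publication, so `d` is a parameter everywhere and
  the 460-predictor identity is asserted at `d = 225` as pure length
  arithmetic. Non-finite descriptor values are flagged, never zeroed; a
  compound with more than 10 % non-finite entries is rejected.
* **Descriptor block order** follows canonical id order of the pair at
  train and screen time alike, making `build_pair_vector()` symmetric in
  its arguments.
* **Negative inhibition** in the kinetics module is reported as-is (an
  activator or artifact is information); the initial-phase slope is OLS
  *with* intercept over the first 10 points, since the zero-shift does
  not force a through-origin fit.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the full protocol on the
150-compound default library (11,175 pairs, five splits, 10×5-fold RF
tuning per split) and smaller 10–18-compound fixtures for the exact
oracles. The combinatorial identities of the 1,410-compound protocol are
checked exactly on id vectors without featurization.

## Known limitations

* Single shared target defines `Match`; multi-target structure and
  target-family holdout splitting are out of scope.
* The seven fingerprint implementations follow the *kinds* used in the
  reference protocol, not any specific toolkit bit-for-bit; absolute
  Tanimoto medians are therefore not comparable across toolkits.
* The MCS kernel is exact only within its time budget; pathological
  graph pairs fall back to exclusion, never to a silent lower bound.
* Probability estimates from the class-weighted forest are not
  calibrated; only their ranking and the fixed 0.5 threshold are used.
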