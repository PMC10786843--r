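---
title: "Methods: consensus labeling, evaluation metrics, and segmentation in crowdcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus labeling, evaluation metrics, and segmentation in crowdcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdcell)
```

`crowdcell` analyzes crowd-labeled blood smear cells: non-expert workers
classify single-cell images into *circular* (normal discocytes),
*elongated* (sickle forms) and *other* deformations, and the package
aggregates, evaluates and models those labels. This vignette documents
the statistical and numerical choices behind each stage, what the
synthetic generators do and do not emulate, and the known limitations.

## Plurality consensus

Each cell is voted on by a panel of `k` workers (default `k = 5`, odd).
The consensus label is the plurality class, accepted only when its count
reaches `floor(k/2) + 1` — 3 of 5. With three classes and five votes the
multiset of counts takes one of five configurations, `5`, `4-1`, `3-2`,
`3-1-1` and `2-2-1`, and only the last fails the threshold and produces
a *no answer*. The threshold makes the winner unique whenever it is
reached, so no tie-breaking rule is needed.

Design choices:

* **Generalized panel size.** The rule is implemented for any odd
  `k ≥ 3` so the independence model (below) can be explored at other
  panel sizes; 5 remains the default everywhere.
* **Strict panels.** A cell with fewer or more than `k` votes is an
  error, not a partial aggregate: silently aggregating incomplete panels
  would make agreement levels incomparable across cells.
* **Strict labels.** Label strings are parsed case-insensitively from
  the three known classes; anything else is an error. Coercing unknown
  labels (to `NA` or to a default class) would corrupt confusion counts
  downstream.

Agreement level (5, 4 or 3 supporting votes) is retained on every
outcome and used to stratify evaluation, since full agreement carries a
much lower error probability than a bare 3-vote consensus. In the
bundled benchmark tables of 848 cells, the 3-agree and no-answer strata
together — the cells that would be referred back to a specialist — make
up 159/848 ≈ 19% of the total.

## Evaluation metrics

All metrics are computed from a confusion matrix with ground truth in
rows and predictions in columns, in the fixed class order (circular,
elongated, other). When scoring consensus output, no-answer predictions
occupy a dedicated column: they stay in the denominator and never count
as correct, so "aggregated" accuracy reflects the full cell set.

* **Per-class accuracy** is the row-normalized diagonal (recall). A
  class with no ground-truth cells reports `NA`, never 0.
* **SDS-score** (sickle-cell diagnosis support) encodes the clinical
  asymmetry of errors: confusing the two deformed classes with each
  other still alerts the specialist, so those confusions join the true
  positives in the numerator `N`; any error involving the circular class
  (a deformed cell called normal, or vice versa) goes into `Ec`; the
  score is `N / (N + Ec)`. Merging the deformed classes leaves the score
  unchanged, which is a useful internal consistency check. With a
  no-answer column, a no-answer on a circular cell counts in `Ec` (the
  cell is flagged without cause) while a no-answer on a deformed cell
  enters neither term — the score weighs only circular-related
  mistakes.
* **Class-balance accuracy (CBA).** Two variants ship. The variant that
  reproduces the benchmark tables is macro-averaged recall
  (`cba_macro_recall()`); the max-marginal literature form
  `mean(diag / max(row sum, column sum))` is provided as
  `cba_mosley()` and documented as numerically different (0.584 vs
  0.719 on the bundled individual-vote matrix). We prioritize value
  reproduction over nomenclature and label both clearly.
* **Matthews correlation.** The binary form is used for the merged
  circular-vs-deformed matrix. The multiclass generalization
  (Gorodkin's R_K) is provided and tested against the one-hot Pearson
  correlation identity; note that on the bundled 3-class matrix it
  yields 0.621, which does not match the 0.6748 printed alongside the
  benchmark tables — the provenance of that printed value is unknown,
  and the package makes no attempt to reproduce it.
* **F-measure** ships in macro, support-weighted and micro forms.
  None of the three reproduces the benchmark's printed F values either
  (0.661 / 0.844 / 0.812 vs a printed 0.7802 on the individual matrix);
  the benchmark's F variant is unresolved and deliberately not targeted.
* **Two-class merging** pools the elongated and other rows and columns
  into a *deformed* class, preserving totals and the circular marginals.

Reported percentages are rounded half-up to two decimals to match
table conventions; raw fractions are always retained.

## The independence model

For a class on which each worker is individually correct with
probability α, and assuming votes are independent given the true class,
the consensus is correct whenever at least 3 of 5 workers are correct:

P(consensus correct) = α⁵ + 5·α⁴(1−α) + 10·α³(1−α)²,

the tail of a Binomial(5, α) at its majority threshold, implemented for
general odd `k` as `P(X ≥ floor(k/2)+1)`. The binomial coefficients are
necessarily C(5,5) = 1, C(5,4) = 5 and C(5,3) = 10 — the terms "5
correct", "4 correct of 5", "3 correct of 5" — and the implementation is
verified against an exhaustive enumeration of all correct/incorrect vote
patterns for `k ≤ 7`.

The model deliberately ignores the composition of the wrong votes: with
fewer than 3 correct votes a consensus on a *wrong* label may or may not
form (3-2 vs 2-2-1 among the errors), but the model counts all such
panels as failures. It is an approximation of the consensus process, not
an exact computation, and it is exact only in its upper tail behavior.

Its practical use is diagnostic: on the benchmark tables the model
predicts 98.1 / 80.7 / 70.3% consensus accuracy per class from the
individual accuracies, while the observed consensus reached 91.7 / 70.7
/ 64.0%. Independent errors cannot produce such a shortfall (the
simulator confirms agreement within Monte-Carlo error in independent
mode), so the gap is evidence of positively correlated worker errors —
some cells are hard for everyone. `compare_estimate_vs_observed()`
computes this per-class gap on any dataset.

## Chan–Vese segmentation

Single cells are extracted from smear images by minimizing the two-phase
piecewise-constant Mumford–Shah energy

μ·length(C) + λ_in ∫_in (u − c_in)² + λ_out ∫_out (u − c_out)²

over a level-set function φ. The method needs no gradient information
and changes topology freely, so one initial contour finds every cell in
the field. Defaults: μ = 0.2, at most 1000 iterations, λ_in = λ_out = 1.

Numerical scheme (none of this is dictated by the energy itself; the
choices below are the package's own):

* Intensities are rescaled to [0, 1] before segmentation and nothing
  else is done to the image; this makes the mask invariant to constant
  intensity shifts, and region means are reported back in input units.
* Explicit gradient descent on φ with the smoothed Heaviside/delta pair
  of width ε = 1 pixel, curvature by central differences, replicated
  (Neumann) borders, step size `dt = 1` (halving `dt` roughly doubles
  the iteration count without changing the mask).
* φ starts as a `sin(πx/5)·sin(πy/5)` checkerboard — the standard
  scatter-friendly initialization — and is clamped to [−5, 5] so the
  regularized delta keeps the flow bounded.
* Convergence is declared when the mean per-iteration change of φ over a
  10-iteration window drops below `tol = 1e-3` per pixel; the window
  makes the criterion robust to single-pixel flicker at the clamp while
  still catching systematic interface drift. On 64–128 pixel synthetic
  scenes convergence typically occurs after 500–700 iterations, well
  under the cap.
* The Chan–Vese energy is tracked at every checkpoint. It decreases
  monotonically once the checkerboard transient (the first few
  checkpoints, where the discrete perimeter estimate of the
  high-frequency initialization is unreliable) has dissipated, and the
  converged region means recover the two levels of a piecewise-constant
  image to well within 1%.
* **Foreground polarity:** the region whose mean differs most from the
  image-border mean is declared foreground. Smear images have a dominant
  background touching the border, so this selects the cells whether they
  are darker or brighter than the field.

Cleanup removes 8-connected components smaller than `min_area` (default
64 px at the synthetic generator's scale — cells are drawn with radii
5–9 px, giving areas well above 64, while noise specks fall below; the
threshold is configurable for other scales). Each surviving component
becomes a crop with a 2-pixel margin, 1-based inclusive bounding boxes
(the R matrix-indexing convention), and deterministic ids ordered by
(top, left).

## Synthetic data

The generators exist so that every stage — segmentation, voting,
aggregation, scoring — can be tested against known ground truth.

**Scenes.** `generate_scene()` renders dark cells (intensity 0.25) on a
light background (0.9) with additive Gaussian noise (default sd 0.02 on
the [0, 1] scale): discs for circular cells, capsules with aspect ratio
≥ 3:1 for elongated cells, and star-shaped radial-perturbation blobs for
"other". The default class mix (0.7, 0.2, 0.1) mirrors the imbalance of
smears from SCD patients, where normal cells dominate. Cells are placed
by rejection sampling with a 2-pixel clearance so each planted cell is
its own connected component, and placement failure is a loud error
reporting the achieved count. What the scenes do *not* emulate:
overlapping or touching cells, staining gradients, out-of-focus blur,
debris, and the texture of real erythrocytes. Passing segmentation tests
on these scenes therefore demonstrates the correctness of the
implementation, not clinical-grade performance on real smears.

**Votes.** `simulate_votes()` draws each worker's vote from the row of
their 3×3 response matrix for the cell's true class.
`profiles_from_confusion()` builds profiles from an observed
individual-vote confusion matrix, so the default simulation regime
inherits the empirically observed error structure (e.g. circular-cell
errors split 58:351 between elongated and other). The optional
`difficulty_model(pi_hard, hard_penalty)` draws a per-cell Bernoulli
"hard" latent shared by all workers; on hard cells every worker's
diagonal accuracy is multiplied by `hard_penalty` with the off-diagonal
mass rescaled proportionally. This is the minimal mechanism that
produces positively correlated errors and an observed-below-predicted
consensus gap; richer mechanisms (worker-specific biases, difficulty
that depends on morphology) are out of scope. There is no
worker-reliability weighting anywhere (no Dawid–Skene style EM): the
consensus rule under study is unweighted plurality.

All generator randomness flows through a mandatory integer seed, and
identical seeds give byte-identical outputs.

## Problem sizes and tolerances in the test suite

The exhaustive consensus oracle enumerates all 3⁵ = 243 ordered panels.
Monte-Carlo comparisons against the binomial model use 20,000 simulated
cells in the headline check (standard error ≈ 0.1 percentage points at
α ≈ 0.87) and 4,000 cells in auxiliary property tests, with 3-standard-
error acceptance bands throughout. Segmentation properties use 64–128
pixel images (a 256-pixel scene is exercised in development but not in
the default suite) with Dice ≥ 0.99 required on noiseless discs and
≥ 0.95 on noisy multi-cell scenes. Statistical tests are seeded, so the
suite is deterministic.

## Known limitations

* The consensus model assumes exactly `k` votes per cell and exchangeable
  workers; there is no modeling of worker identity, fatigue or learning.
* The independence model's "at least 3 correct" event slightly
  understates consensus accuracy when wrong votes split, as noted above.
* The segmentation is two-phase: overlapping cells merge into one
  component, and no splitting (watershed or otherwise) is attempted.
* The benchmark tables bundled with the package are summary counts, not
  per-cell records; per-stratum confusion matrices are therefore not
  reconstructible from them, and stratum-level metrics are exercised on
  simulated data only.
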