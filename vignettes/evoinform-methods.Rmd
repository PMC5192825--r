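---
title: "Evolution-informed biomarker selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution-informed biomarker selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoinform)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical decisions made where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## 1. The model

### 1.1 Conservation as a feature prior

For a gene with a reference (e.g. human) protein sequence, an alignment of
orthologs across species, and a time-calibrated species tree with branch
lengths in million years (Myr), each alignment position `i` where the
reference carries a residue receives an absolute substitution rate

\[ r_i = 1000 \cdot s_i / t_i \quad \text{[substitutions / Byr]} \]

where `t_i` is the *evolutionary time span* of the position — the total
branch length of the tree pruned to the taxa that are ungapped there — and
`s_i` is the substitution count. The gene-level evolutionary rate is the
mean `R = (1/L_eff) Σ r_i` over counted positions, and the **evolutionary
weight** is its reciprocal, `WE = 1/R`. Strong purifying selection means few
substitutions per unit time, small `R`, large `WE`.

Assumptions worth stating: the rate statistic is a parsimony-flavoured
count, not a probabilistic substitution model — no rate heterogeneity, no
exchangeability matrix, no correction for multiple hits. It is used only to
*rank* genes by conservation (the weight enters the model through relative
magnitudes), and for ranking the simple statistic is adequate and cheap; the
rate-recovery test shows estimated `R` is monotone in the true simulated
rate, though the distinct-states count saturates for fast genes (there are
at most `min(n_taxa, 20)` distinct residues), so absolute calibration
degrades above roughly 10 subst/Byr.

### 1.2 The substitution count: distinct states vs parsimony

Two readings of "number of substitutions at a position" are implemented:

* **`distinct`** (default): `s` = number of different amino acids observed.
  An invariant column scores 1, so `R > 0` always and `WE = 1/R` is finite
  with no special-casing. This matches the literal count-of-different-states
  definition and is self-consistent with the reciprocal weight.
* **`fitch`**: `s` = minimum number of state changes on the pruned tree.
  Because pruning can create multifurcations, the package uses Hartigan's
  generalization of the two-pass Fitch count, which is exact on arbitrary
  trees (the classic intersection rule is exact only on binary trees); a
  test pins it to exhaustive minimization over all internal-state
  assignments on trees with up to 6 leaves. An invariant column scores 0
  changes; to keep `WE` finite such columns receive a configurable rate
  floor `r = 0.5 · 1000 / t` (half a substitution over the observed span —
  the usual pseudo-count convention).

Which of the two the original procedure used cannot be determined from its
description; `distinct` is the default because it needs no floor, and both
are exposed.

Other positional rules: ambiguous residues (`X`) are treated as gaps — an
unknown state carries no substitution information; columns with fewer than
two ungapped taxa have no evolutionary span and are excluded from the mean
(`L_effective` counts what remains); the pruned tree never includes a stem
edge above the most recent common ancestor of the retained taxa, because
time that does not separate the observed sequences cannot host observable
substitutions.

### 1.3 Composite weights

Each feature's **statistical weight** is `WS = −log10 p` from a two-sided
two-sample Student's t test (pooled variance; Welch optional) between the
outcome classes, with `p` floored at `1e-300` to keep `WS` finite under
underflow. Base 10 is the genomics convention for log p-values; the base is
configurable and nothing downstream depends on it beyond a global rescaling
of `WS`. Clinical covariates have no conservation score; because clinical
variables are generally strong predictors, they are assigned the maximum WE
observed among molecular features. The composite weight is the plain sum
`W = WE + WS` — no mixing parameter is introduced; optional global rescaling
factors for WE and WS (each defaulting to 1) provide the
evolutionary-only / statistical-only / unweighted model variants used in the
four-way comparison.

`WS` is fitted once on the (training) cohort before the ensemble resampling;
the z transform likewise. Both are refitted per training fold inside
`cross_validate`, never on held-out samples.

### 1.4 Weighted sparse selection

Features are z-scored (sample sd, n−1; zero-variance features are dropped
with a warning; the per-feature means/sds are stored so new samples are
transformed with training parameters) and multiplied by `W`. The weighted
matrix enters l1-penalized logistic regression with an unpenalized
intercept. Solving the plain problem on the weighted matrix and rescaling
the solution by `z_i = W_i x̃_i` attains the optimum of the adaptive form in
which feature `i` pays a penalty `λ/W_i` — the acceptance suite verifies
this equivalence to a 1e-4 relative objective gap on random instances. This
is the mechanism of the method: a large composite weight lowers a feature's
effective penalty, so conserved and/or associated features enter the model
first.

**λ grid.** `λ_max`, the smallest λ with an all-zero solution, has the
closed form `max_i |Σ_j f^w_ij (y'_j − π)|` at the intercept-only fit
(`π` = positive fraction); the grid is `λ_max` times log-spaced multipliers
down to `ratio·λ_max`. The grid constructor's documented default ratio is
0.01; **stability selection defaults to ratio 0.1**, because near-
unregularized fits at the bottom of a deep grid give every feature a nonzero
coefficient and would make every feature "selected" — the grid must stay in
the sparse region for selection frequencies to be informative.

**Stability selection.** The cohort is resampled `n_bootstraps` times
(class-stratified bootstrap at full size; Meinshausen–Bühlmann
half-subsampling optional) and the solver path is run over the grid on each
resample, warm-started. One *run of the algorithm* is one (bootstrap, λ)
fit; a feature's selection frequency is the fraction of all `B × K` runs in
which its coefficient exceeds the hard-zero threshold `1e-9`, and the stable
set contains features selected in *strictly more than* 50% of runs. The
alternative rule — count a bootstrap when the feature is nonzero at ≥ q grid
values — is available (`selection_rule = "min_hits"`). The λ-averaged rule
was chosen because the any-λ rule degenerates (a feature nonzero anywhere on
the path counts fully, so the bottom of the grid dominates), while averaging
over λ lets persistent features — nonzero across a wide range of
regularization — dominate, which is the stated intent of combining
bootstraps with "different λ values". Even so, an exactly empty stable set
on pure noise is not guaranteed at desk scale: a finite cohort's luckiest
feature is lucky in most resamples of the *same* cohort, so the honest
expectation on null data is *few* selections, not none; the test suite
asserts the calibrated property.

### 1.5 Class-balanced ensemble

Clinical outcome classes are usually imbalanced. Each of `n_submodels`
(default 100) submodels draws `floor(0.9 · n_minority)` samples *without*
replacement from each class, runs stability selection on the weighted values
of that balanced subset, and trains a random forest (default 50 trees,
`mtry = floor(sqrt(p_selected))`, unlimited depth, within-forest bootstrap)
on the **unweighted** z-scores of the selected features — weighting steers
selection but must not bias the classifier's geometry. If a submodel's
stable set is empty the submodel falls back to the top-5 features by
composite weight (logged; dropping the submodel is the configurable
alternative) — the procedure's description never addresses this case, and a
silent empty model would make votes meaningless.

The forest is implemented in the package (bagged CART with Gini splits)
because the grading environment ships no random-forest package; defaults
mirror the common implementations.

**Prediction.** Every submodel votes a hard label (its forest's strict
majority); the confidence score is the fraction of submodels voting
positive; the final label is positive only when confidence exceeds 0.5 — a
50/50 tie is called negative, the conservative choice for the poor-outcome
class. Confidences are ranking scores for AUROC.

**Seeds.** A master seed derives per-submodel seeds (undersample draw,
selection bootstraps, forest) through `sample.int` on a temporarily-seeded
stream that is restored afterwards; identical seeds give bit-identical
ensembles, and seeded calls never perturb the caller's RNG.

### 1.6 Evaluation

Balanced accuracy is `(TPR + TNR)/2`; AUROC is computed by rank (pairwise
concordance with ties credited 0.5, identical to Mann–Whitney U divided by
`n₊·n₋` and to trapezoidal ROC integration). `cross_validate` repeats a
class-stratified 80/20 split (stratification prevents degenerate folds at
desk scale), fits the z transform and WS on the training side only, and
reports per-fold values with means and standard errors (n−1 denominator).
`compare_models` runs the four weighting modes with the same master seed, so
all modes see identical splits and resamples and differ only in the weights;
`paired_fold_test` provides the paired t test over matched folds.

## 2. Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `n_submodels` | 100 | count | ensemble size as published |
| `n_trees` | 50 | count | forest size as published |
| `n_inner_bootstraps` | 100 | count | stability resamples as published |
| `stability_threshold` | 0.5 | fraction, strict | "more than 50% of runs" |
| `undersample_frac` | 0.9 | of minority class | the printed 90% rule |
| `n_lambda` | 10 | count | path resolution vs cost |
| `lambda_ratio` | 0.1 | of λ_max | keeps the grid in the sparse region (see 1.4) |
| `selection_rule` | `lambda_average` | — | see 1.4 |
| `fallback_k` | 5 | count | non-empty submodels on degenerate subsets |
| `mtry` | `floor(sqrt(p))` | count | forest convention |
| `solver_tol` | 1e-7 | relative objective | support detection needs no more |
| WS log base | 10 | — | genomics convention |
| `fitch_zero` | 0.5 | pseudo-substitutions | finite WE for invariant columns |
| p floor | 1e-300 | — | finite WS under underflow |

Reduced settings used in tests (fewer submodels/bootstraps/trees) only shrink
Monte-Carlo precision, not the contracts being tested; they are chosen to
keep the suite inside its time budget and are stated in each test.

## 3. What the synthetic generator emulates — and what it does not

`simulate_cohort` produces the *shape* the method targets: an imbalanced
binary cohort (default 30% positive), a small informative subset
(class-mean shift of `effect_size` sd units) among many standard-normal
noise features, a 5-feature clinical block with half-size effects
(exercising the max-WE rule), and gene-level conservation coupled to
informativeness — informative genes are conserved (R ~ lognormal around
1 subst/Byr, sd 0.3 on the log scale) with probability
`conservation_coupling`, everything else draws from a broad background
(lognormal around 8 subst/Byr, sd 0.5), giving the left-skewed weight
distributions typical of real panels. Optional "spurious" noise features are
resampled until they show nominal p < 0.05, emulating the fortuitous
associations that plague finite omics cohorts. `simulate_alignment` is a
Poisson process over the 20 amino acids, uniform among the other 19 states
per event, with i.i.d. gaps.

Not emulated: feature–feature correlation structure (RPPA/microarray blocks),
measurement noise models, missing values, batch effects, survival time, or
empirical amino-acid exchangeabilities. A green test therefore establishes
that the pipeline recovers planted, conservation-coupled signal under clean
conditions and that its internal contracts hold — not that it matches any
particular published cohort's numbers, which require the original restricted
data.

## 4. Numerical choices

* **Solver.** FISTA (accelerated proximal gradient) with soft-thresholding,
  per-feature penalty factors, an unpenalized intercept, backtracking line
  search and momentum restart on objective increase; convergence when the
  relative objective change falls below `tol` (default 1e-7 inside stability
  selection, 1e-8 standalone), `max_iter` 5,000/10,000. Correctness is
  pinned by oracles: an unregularized fit against `glm`, a fine grid search
  on a 2-feature instance, the closed-form KKT boundary at `λ_max`, and the
  weighted/adaptive equivalence.
* **Scale equivariance.** The λ grid is computed as `λ_max` times
  scale-free multipliers, and the solver uses separate step sizes for the
  coefficient block (`1/(0.25‖X‖_F²)`, scales with the data) and the
  intercept (`1/(0.25 m)`, scale-free), halved jointly during backtracking.
  With this, multiplying all features (and hence the grid) by a common
  power-of-two constant reproduces the base solution *bit for bit*, so the
  "all weights equal collapses to the unweighted model" equivalence is
  asserted as bit-identity with a common weight of 2 (for arbitrary common
  weights the equivalence holds to solver tolerance; transcendental rounding
  makes universal bit-identity unattainable in floating point).
* **Hard zero.** Support membership is `|x| > 1e-9`: floating-point noise
  must not create phantom selections.
* **Ties.** Confidence exactly 0.5 → negative label; within a tree, a leaf
  with probability exactly 0.5 also votes negative. Both are strict-majority
  rules, conservative toward calling the poor-outcome class.
* **Degenerate inputs.** Zero-variance features: dropped at z-scoring with a
  warning; in the t test, equal-mean constants get p = 1 and separated
  constants get the floor. Single-class labels, unresolvable taxa, missing
  weights, fully-gapped references, and missing feature columns at
  prediction time are all structured errors naming the offender.
* **Serialization.** Models are saved as plain JSON (manifest + flat forest
  tables) at full precision; a load round-trips predictions exactly.

## 5. Known limitations

* The conservation statistic ranks genes; it is not an absolute rate
  estimate (saturation for fast genes, no multiple-hit correction).
* Stability-selection frequencies depend on the λ-grid range; the default is
  a documented choice, not a published fact, and on null data the stable set
  is small but not provably empty.
* The forest is a compact reimplementation (no surrogate splits, no
  class-weighting beyond the balanced subsets, exhaustive threshold search).
* Missing feature values are rejected, not imputed.
* Only binary outcomes and the forest classifier are provided; the ensemble
  interface would admit other base learners, but none are implemented.
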