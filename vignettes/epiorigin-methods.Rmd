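---
title: "Predicting tissue-of-origin from regional mutation density: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tissue-of-origin from regional mutation density: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiorigin)
```

## The model

Somatic mutation rates vary regionally with chromatin state: heterochromatic,
late-replicating regions of the cell-of-origin accumulate more mutations,
active regions fewer. `epiorigin` exploits this by regressing a sample's
per-window mutation counts on a panel of per-window ChIP-seq read counts
(one feature per histone mark per tissue/cell type) and asking which single
feature survives a greedy model-reduction procedure.

Formally, with $y_i$ the mutation count in 1-Mb window $i$ and $x_{ij}$ the
read count of chromatin feature $j$, a boosted ensemble of depth-limited
regression trees minimises the squared-error objective with L2 leaf
regularisation. Each split is chosen by the regularised gain

$$\mathrm{gain} = \tfrac12\!\left(\frac{G_L^2}{H_L+\lambda}
  + \frac{G_R^2}{H_R+\lambda} - \frac{G^2}{H+\lambda}\right) - \gamma,$$

where $G$ and $H$ are sums of first and second loss derivatives (for squared
error, residual sums and row counts). The feature's *importance* is the
total gain of all splits that use it. Ranking proceeds in two stages:

1. **Screening:** 10-fold cross-validation; the model is fit on each
   training split and importances are averaged across folds; the top 20
   features are kept.
2. **Backward elimination:** the model is refit on the surviving set (full
   data, fixed hyperparameters) and the minimum-importance feature is
   removed, until one survives. The survivor is rank 1, and its annotated
   tissue/cell type is the predicted origin.

The random-forest baseline replaces the booster with a 1000-tree regression
forest and gain importance with classical out-of-bag (OOB) permutation
importance: for each tree, each feature's values are permuted within the
tree's OOB rows and the mean OOB MSE increase across trees is the score.
Elimination then proceeds identically.

## Tunable parameters

| parameter | default | grid | role |
|---|---|---|---|
| `learning_rate` | 0.5 | 0.05–1.0 (9 values) | shrinkage per boosting round |
| `n_estimators` | 20 | — | boosting rounds |
| `gamma` | 0 | 0, 0.5, 1, 2 | minimum split loss |
| `max_depth` | 6 | 1, 3, 6, 8 | tree depth |
| `cv_folds` | 10 | — | screening folds |
| `n_trees` (forest) | 1000 | — | forest size |

Off-grid values are rejected unless explicitly overridden, keeping runs
comparable to the published configuration space. Two parameters have no
published value and follow the boosting literature's defaults: the L2 leaf
penalty $\lambda = 1$ and `min_child_weight` = 1.

## Interpretation points resolved here

The published description leaves three details open; this implementation
fixes them as follows and records the choice in the output metadata:

* **Importance definition.** "Importance" is taken as *total gain* (loss
  reduction summed over splits), the standard regression-relevant choice;
  not split count or cover. The forest uses permutation importance as
  described above, with the sign convention permuted-minus-untouched so
  larger means more informative.
* **Cross-validation scope.** CV is applied to the screening stage (the fit
  on "the complete set of variables"); elimination refits use the full data
  without CV. Per-step CV would multiply cost tenfold with no stated
  mandate; it remains available via `eliminate_with_cv`.
* **Ties.** Features the trees never split on (importance exactly 0) are
  eliminated before any positive-importance feature, among themselves by
  ascending feature id. Determinism requires *some* rule; alphabetical is
  auditable.

Two further conventions: ChIP-seq reads are assigned to the window
containing their midpoint (counted exactly once at boundaries), and windows
are dropped when more than `excluded_fraction_max` (default 0.5) of their
bases fall in exclusion intervals — the source material names no numeric
rule, so the threshold is surfaced as a parameter rather than hard-coded.
An "enhancer-containing" window is one overlapping an enhancer interval by
at least 1 bp; full containment is not required.

## Seeds and reproducibility

All randomness flows from integer seeds through a splitmix-style derivation
(`seed_derive()`): CV fold assignment, forest bootstraps and permutations,
subset draws, and the synthetic generator each consume an independent
derived stream. Per-iteration subset seeds are derived as
`hash(seed, size, iteration)`, so extending a sweep with new sizes never
perturbs existing iterations. The boosted fit itself is deterministic given
the data (exact greedy splits, no subsampling); repeated runs differ only
through the fold assignment, which is the stochastic element the
reproducibility analysis (`repeat_predictions()`) quantifies. Identical
seeds reproduce every output file byte for byte.

## The synthetic world

Real inputs are controlled-access, so tests run on a generator that states
a world rather than fitting one:

* Each tissue $t$ has a latent standard-normal per-window profile $u_t$.
  Feature $f$ of tissue $t$ renders $\rho u_t + \sqrt{1-\rho^2}\,e_f$
  (default $\rho = 0.9$, matching the strong within-tissue coherence of
  real histone tracks) as negative-binomial read counts (mean 500 per
  window, dispersion 10 — a realistic coverage scale for 1-Mb bins).
* Mutation counts are Poisson with log-rate $a + b z_i + \varepsilon_i$,
  where $z$ is the standardized driver-tissue profile, $b = -1$ by default
  (mutation depletion in the origin tissue's active chromatin; tree rankers
  are sign-agnostic), $\varepsilon \sim N(0, 0.3)$ adds over-dispersion,
  and $a$ is set analytically so the mean density equals
  `baseline_density` (default 1 mutation per Mb, the normal-clone regime;
  adult stem cells sit nearer 0.1 and solid tumors at 5+).
* Default scale: 2128 windows on 22 synthetic autosomes, 8 tissues × 8
  features.

The generator reproduces the *statistical skeleton* the method assumes —
a low-rank tissue structure with one profile driving mutation rates — but
not real data's spatial autocorrelation, mutational signatures, replication
timing, or the 673-track, 132-tissue scale of a real compendium. A green
planted-recovery test therefore establishes that the ranking machinery
identifies a dominant chromatin driver under count noise, not that any
particular published accuracy is reproduced; the published cohort numbers
depend on controlled-access data and are out of reach by design.

With these defaults the planted signal is strong: eight correlated tracks
carry the driver tissue, and recovery is essentially perfect even at
density 0.1/Mb, where single-feature attribution already degrades. The
density-dependence checks in the test suite are therefore directional
(sparse must not beat dense; boosting must hold up at low density) rather
than quantitative.

## Numerical choices and degenerate inputs

* Counts are modelled raw (no log transform): tree splits are invariant to
  monotone per-feature transforms, and the squared-error objective on raw
  counts matches "predicting regional mutation density". A `log1p_target`
  option exists for heavy-tailed targets.
* A constant target produces zero gradients, no splits, and all-zero
  importances; ranking then falls back to the alphabetical tie rule.
* Split thresholds are midpoints between adjacent distinct values; gains
  must exceed the incumbent by 1e-12 to replace it, so float noise cannot
  reorder equal candidates.
* Forest trees with no out-of-bag rows (possible at very small n) are
  skipped for importance with a warning.
* `n_trees` defaults to the published 1000 but test suites run 50–200;
  permutation importance stabilises well below 1000 trees at the feature
  counts involved, and the elimination order depends only on the argmin.

## Known limitations

* Mutation counting is position-only (no allele or signature awareness);
  stratifying by mutational signature is explicitly out of scope.
* Inputs are assumed on one genome build; no liftover is performed.
* The forest baseline matches the *described* algorithm, not any specific
  legacy implementation bit-for-bit; comparisons are statistical.
* With fewer than ~10 windows per CV fold the screening stage is unstable;
  the package refuses to screen when rows < folds.
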