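---
title: "Comparative biomarker panel refinement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative biomarker panel refinement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Whole-blood transcriptome classifiers for acute kidney-transplant rejection
(and case-control classification in transcriptomics generally) are built
from a long pipeline of analytical choices: how the probe-set space is
pre-filtered before any class comparison, how candidate features are ranked
and filtered into panels, which classifier is trained, how its single
tuning parameter is selected, and how performance is estimated without
optimistic bias. `markergrid` implements that pipeline as a factorial
experiment: five unsupervised pre-filters x five ranking/filtering rules x
eight classifier configurations, all evaluated under multiple-partition
stratified nested cross-validation, so the contribution of each analytical
choice can be compared on equal footing.

The design target is a balanced case-control cohort: 24 cases with
biopsy-confirmed acute rejection (class `AR`) and 24 matched non-rejecting
controls (`NR`), profiled on a 54,613-probe-set expression array and
analyzed on the log2 scale.

# Pipeline stages

## Summarization (module `summarize`)

Probe-level intensities are quantile-normalized across arrays
(`quantile_normalize()`, ties resolved by the mean of the reference values
over the tied rank span) and summarized per probe-set by median polish
(`median_polish_summarize()`: row sweeps first, at most 10 sweeps,
tolerance 0.01; the per-array summary is the overall plus column effect).
This mirrors the normalization and summarization stages of the RMA recipe.
The convolution background-correction step is deliberately omitted: the
package operates on log2-scale intensities (synthetic or pre-corrected),
where that step has no meaning.

## Pre-filters (module `prefilter`)

All five filters are label-blind and applied once, before any class
comparison, each defining an "analysis data set":

* **ECMR** keeps the `floor(N/2)` features with the largest inter-quartile
  range, classes pooled; ties broken by feature id so results are
  reproducible. On 54,613 features it keeps exactly 27,306.
* **BI2005** raises all values below 5 to 5, then keeps features whose
  clamped maximum is at least 7.25 (inclusive). The clamped matrix is the
  analysis data set for this arm — downstream differential expression in
  this arm sees clamped values.
* **PVAC-style consistency** scores each probe-set block by the share of
  its row-centered variance captured by the first principal direction
  across arrays; blocks scoring at least 0.5 (a package default — exposed,
  since no published threshold exists for this surrogate statistic) are
  kept. A block of probes tracking a shared signal scores near 1; pure
  probe noise scores near 1/min(probes, arrays).
* **FARMS-style informative/non-informative calls** fit a one-factor model
  value(p, j) = mean_p + loading_p * z_j + noise by alternating least
  squares with a quadratic penalty on the loadings, and score
  informativeness as var(loading * z) / (var(loading * z) + mean residual
  variance). This is a documented surrogate for the original Bayesian
  factor-analysis formulation: the selection contract (informative vs not)
  is preserved, the posterior machinery is not.
* **PROOF1** is a configurable ordered conjunction of rules covering the
  three criterion families of the original semi-automated approach:
  expression cutoffs, annotation requirements, and within-class robustness
  (coefficient-of-variation limits). The original's precise cutoffs are
  not published, so the shipped default chain (median log2 expression at
  least 9.35, feature annotated) targets a retained fraction near 10% on
  default synthetic cohorts, matching the proportion the most restrictive
  published filter retains (5,619 of 54,613). A time-course criterion
  cannot apply to single-timepoint data and is unsupported.

## Differential expression (module `de`)

`moderated_t()` computes, per feature, the pooled two-group residual
variance s_g^2 on d_g = n - 2 degrees of freedom and shrinks it toward a
common prior: s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g). The prior
(d0, s0^2) is estimated by method of moments on the log residual
variances (matching their mean and variance to the moments implied by a
scaled F distribution), with the trigamma inversion solved by monotone
bisection to 1e-8. The moderated t is logFC / (s~_g sqrt(1/n1 + 1/n2)) on
d0 + d_g degrees of freedom, two-sided; d0 = Inf (homoscedastic features)
falls back to the normal limit. logFC is case minus control, and the
reported natural-scale fold-change is 2^|logFC| with an Up/Down direction.
Benjamini-Hochberg adjustment (`bh_adjust()`) gives the FDR column every
ranking rule consumes. The implementation is cross-checked in the test
suite against limma's empirical-Bayes pipeline on random data; limma is
never the implementation path.

## Ranking rules (module `panels`)

Five rules map a differential-expression table (plus, for the SVM rule,
the training expression data) to an ordered panel. FDR thresholds are
strict (`<`), fold-change thresholds inclusive (`>=`):

* `FDR50` — top 50 by FDR.
* `COMBO0.05` — all FDR < 0.05, padded with the next most significant
  features to at least 50 and truncated to the 500 most significant.
* `FDR0.10.FC0.5` — FDR < 0.10 and |logFC| >= 0.5 (no size bound).
* `FC0.5.TOP50` — |logFC| >= 0.5, then the 50 lowest FDR (fewer accepted
  if fewer pass).
* `FDR0.10.RFE50` — FDR < 0.10, then a one-shot linear-SVM weight ranking
  (cost 1, features standardized on the training samples only) keeping
  the 50 largest |weight|; all features returned when 50 or fewer pass
  the FDR filter. The reduction is deliberately one-shot, not iterative
  elimination.

Inside cross-validation, differential expression and the panel rule are
recomputed on every training fold; nothing from a test fold ever touches
panel construction (verified by a dedicated leakage test).

## Classifiers (module `clf`)

Eight configurations behind one contract — train on (expression, labels,
panel), return the probability of `AR` — each tuning exactly one
parameter, grids ordered most-to-least regularized:

| method | tuned parameter | default grid | fixed |
|---|---|---|---|
| EN-0.10/0.50/0.90 | lambda | 30 log-spaced, 10 to 1e-3 | alpha |
| LDA | n top features (FDR order) | 1..6, 8, 10, 15, 20, 30, 50 | — |
| PAM | shrinkage delta | 30 fractions of max \|d\|, 1 to 0 | — |
| RF-1 | (none) | — | ntree = 500 |
| SVM | cost | 2^-5 to 2^5, powers of 4 | linear kernel |
| XGBoost | boosting rounds | 10, 25, 50, 100, 200, 300 | depth 2, eta 0.1 |

Grid densities are design choices: the one-SE rule selects at the
regularized end of the plateau, so refining the LDA grid beyond small n or
the SVM cost grid beyond factor-4 steps changed no selection in practice
while costing measurable compute; all grids are configurable.

The shrunken-centroid classifier is implemented natively:
d_ik = (centroid_ik - overall_i) / (m_k (s_i + s0)) with
m_k = sqrt(1/n_k - 1/n) and s0 the median pooled within-class sd;
deviations are soft-thresholded at delta, centroids rebuilt, and samples
scored by delta_k(x) = sum_i (x_i - centroid'_ik)^2 / (s_i + s0)^2 -
2 log prior_k with probabilities proportional to exp(-delta_k / 2). EN and
PAM (and LDA through its n) perform feature selection; SVM, RF and
XGBoost score the full panel.

SVM probabilities come from a Platt-style monotone logistic mapping fitted
on training-fold decision values (any monotone calibration preserves AUC;
the mapping is fitted by a small damped Newton with a 1e-8 ridge so
separable folds saturate gracefully). The SVM classification kernel is
linear, matching the kernel of the RFE ranking step. Class priors are
empirical training-fold frequencies. RF and XGBoost are seeded from the
master seed, so repeated runs are identical.

## Cross-validation and selection (module `cveval`)

`make_folds()` builds m stratified partitions of k folds (default 5 x 8):
within each class, samples are shuffled by a seeded stream and dealt
round-robin, so a 24 + 24 cohort at k = 8 gives every fold exactly 3 cases
and 3 controls. Metrics per held-out fold: AUC by case-control pair
concordance (ties count half), and error/sensitivity/specificity at a 0.5
probability threshold (scores at or above 0.5 classify as case; the
threshold reflects the balanced design and symmetric costs and is never
optimized).

Selection uses either the extreme value or the one-standard-error rule:
among grid values whose k * m-fold mean is within one SE of the best, the
most regularized (earliest in grid order) is chosen. The SE of a CV mean
is sd over the k * m fold values divided by sqrt(k * m).

Flat CV (`tune_flat()`) reuses the same folds for tuning and estimation —
optimistically biased after selection. Two antidotes are implemented:

* **Nested CV** (`nested_cv()`, and the engine inside `marker_grid()`):
  per outer fold, tuning runs entirely within an inner stratified plan
  (default 8 folds, 1 partition — the inner partition count is a package
  default, exposed) built on the outer-training samples; the model trained
  at the inner selection is scored once on the outer test fold, and k * m
  outer metrics are aggregated. Untuned RF skips the inner loop, so its
  flat and nested estimates are identical by construction.
* **Optimism bias correction** (`bias_correct()`): B is the mean over
  folds of the gap between each fold's best grid value and the overall
  selection, clipped at zero; corrected = flat - B for maximized metrics
  and flat + B for error. (The orientation follows the cited
  classification-error correction; for error the fold-best is the fold
  minimum, so B is again nonnegative and the corrected error is never
  smaller than the flat estimate.)

Degenerate folds (single-class, undefined AUC) are excluded and the
estimate flagged partial, never silently imputed; they cannot arise under
the stratified plan but the path exists for user-supplied designs.

## The grid and aggregation (modules `cveval`, `aggregate`)

`marker_grid()` enumerates the full cartesian grid (5 x 5 x 8 = 200
combinations by default), sharing per-fold differential-expression tables
across rules and per-fold panels across classifiers, and reusing each
outer-fold grid fit for both the flat estimate and the nested outer score,
which keeps the factorial tractable on one CPU. Per combination it
reports flat, nested and bias-corrected metrics, the selected parameter,
the final model trained on all samples at the flat selection, and
held-out per-sample probabilities averaged over partitions — a 48 x 200
score matrix (9,600 entries) in both nested and flat variants.
Combinations that fail (e.g. an empty panel in some fold) are quarantined
with their reason and reported as NA rows; the grid continues.

`build_inclusion()` turns the 200 final panels into a binary
feature x combination matrix using post-classifier selections where the
method selects features (EN nonzero coefficients, PAM survivors, LDA's
top n) and the rule panel otherwise — the convention under which a
feature's inclusion count across combinations is informative rather than
constant within a rule. `frequency_filter()`, `gene_summary()` (group
means, natural-scale fold-change, direction, count, fraction) and
`score_summaries()` (per-sample medians/IQRs across combinations and
discordance flags at 0.5) provide the reporting layer.
`enrich()` performs hypergeometric over-representation with BH correction;
the gene ratio is the overlap divided by the number of candidate genes
mapped to any set. The recommended universe is the pre-filtered gene list
of the arm under analysis with candidates at FDR < 0.1 (configurable); a
gene qualifies if any of its probe-sets qualifies.

# The synthetic cohort generator (module `simdata`)

No real cohort ships with the package, so `simulate_cohort()` generates
one with the statistical structure the pipeline assumes:

```
intensity(probe p of set i, array j) =
  baseline_i + affinity_p + effect_i * activation_j
  + shared_signal_ij + noise_ipj
```

* `baseline_i` ~ N(7.5, 1.5) for null features; planted features draw
  baselines from N(8.5, 1.0), the expressed range where array DE is
  observed (reported group means for recurrent rejection markers span
  roughly 6.5–11.2 log2 units).
* `effect_i`: a `de_fraction` (default 5%) of probe-sets carry signed
  log2 effects with magnitudes uniform in [0.5, 1.5], half up / half down
  (configurable).
* `activation_j = case_j + N(0, het_sd)` is a per-sample latent
  disease-activity score through which *all* planted features express
  their effect. This models two facts about real cohorts that independent
  Gaussian features cannot reproduce simultaneously: differentially
  expressed genes are co-regulated modules, and patients vary in severity
  — some cases present weakly, which bounds the achievable AUC of any
  classifier and produces case samples that persistently score below 0.5.
  With `het_sd = 0` the model reduces to a fixed class effect. The default
  0.4 was calibrated (once) so that grid AUCs land in the 0.88–0.98 range
  reported for this study design while preserving strong univariate
  differential expression; it is the package's noise-level answer to a
  question the source cohort leaves open.
* `shared_signal_ij` ~ N(0, signal_sd = 1.0) is the biological
  array-to-array variation shared by all probes of a set;
  `noise_ipj` ~ N(0, noise_sd = 0.7) is independent probe noise. A
  fraction `frac_inconsistent` (default 30%) of probe-sets replace the
  shared signal with independent per-probe noise of matched total
  variance: their intensity distribution is unchanged (so
  intensity-based filters are blind to them) but their probe profiles
  disagree, which is exactly what the consistency filters detect.
* A per-feature log-normal amplitude (sd 0.3 on the log scale) scales
  shared signal and noise together, giving heteroscedastic features (so
  the empirical-Bayes variance prior is finite and informative) without
  touching consistency scores.
* The probe-set-level matrix is the exact noise-aggregate of the
  probe-level draws (mean of the per-probe noise), i.e. the
  summarization-free truth the median-polish step estimates; with
  `probe_level = FALSE` an equivalent-variance noise term is drawn
  directly and the probe blocks are skipped.
* Every random stream (labels, effects, baselines, noise, folds, gene
  sets) derives its own sub-seed from the master seed, so adding a stream
  never perturbs earlier ones and identical (seed, config) give
  byte-identical outputs, including written GMT files.

`simulate_gene_sets()` emits a GMT collection whose first
`n_enriched_sets` sets draw at least half their members from planted
genes (set sizes capped so that is feasible); the rest draw uniformly.

**What passing tests do and do not show.** The generator emulates the
study's design parameters and the qualitative structure the methods
assume. It does not model batch effects, spatial artifacts, RNA
degradation, non-Gaussian heavy tails, or realistic gene-gene correlation
beyond the single activation axis — so green tests certify that the
machinery is correct and honest (nested estimates unbiased under the
null, optimism positive under tuning, planted structure recovered), not
that any particular AUC would transfer to a real cohort.

# Numerical choices and degenerate inputs

* Tie-breaks are deterministic everywhere (feature id lexicographic);
  quantile-normalization ties take the mean reference over the rank span.
* Zero-variance features never divide by zero: the shrunken variance is
  positive whenever s0^2 > 0; features constant in both groups get t = 0,
  p = 1.
* PAM's s0 guards zero within-class sds; full shrinkage collapses
  predictions to the class priors exactly.
* Empty panels raise an error in classifiers and quarantine a grid
  combination; missing features at prediction time raise an error rather
  than being imputed.
* Problem sizes in the shipped tests and acceptance script: the factorial
  grid runs on cohorts of 600–1,000 probe-sets with 4–5 probes per set
  (the full 54,613-feature space is exercised by the ECMR count check
  and scales linearly); these sizes were chosen as the smallest at which
  every arm of the factorial remains non-degenerate.

# Known limitations

* The FARMS and PVAC filters are surrogate statistics with the same
  selection intent as their namesakes, not reimplementations.
* PROOF1's original criteria are only partially published; the rule chain
  is parameterized rather than guessed, and the time-course criterion is
  unsupported.
* The bias-corrected estimate is a cheap alternative to nested CV, not a
  replacement; its per-fold optimism is noisy at k * m = 40.
* Single-timepoint, two-class designs only; no paired analysis, array
  weights, or multi-factor models.
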