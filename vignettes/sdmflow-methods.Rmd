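---
title: "Methods: bias-aware distribution modelling with sdmflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias-aware distribution modelling with sdmflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Presence-only occurrence records — the dominant data type for
wide-ranging and invasive species — carry two entangled difficulties:
there are no absences to contrast against, and the locations of the
records reflect *where people looked* as much as where the species
lives. Expert monitoring concentrates around long-running field sites;
opportunistic (citizen) reports cluster along roads and settlements.
`sdmflow` implements a complete correlative species-distribution
modelling (SDM) workflow built around those two difficulties, and ships
a virtual-species simulator with known truth so that every stage of the
workflow can be validated quantitatively rather than by eye.

## Pipeline overview

The stages, each an exported function and chained by `run_pipeline()`:

1. **Occurrence preparation** (`prepare_occurrences()`,
   `merge_datasets()`): temporal window filter (default 1970–2012),
   plausibility mask, and cell-level deduplication at the covariate
   grid resolution (1-km cells by default). Merging keeps the expert
   record when a cell holds both sources.
2. **Covariate screening** (`screen_covariates()`): Spearman
   `|rho| >= 0.7` and VIF `>= 3` cutoffs, removing the covariate with
   the lower ecological-priority rank from each violating pair until no
   violation remains. Priorities are explicit configuration, so the
   "keep the ecologically relevant one" judgement is reproducible.
3. **Spatial structure** (`density_surface()`, `ripley_l()`,
   `morans_i()`, `select_resolution()`): a Gaussian-kernel density
   surface proxies sampling effort; Ripley's L diagnoses clustering
   against a complete-spatial-randomness envelope; a global Moran's I
   scan across aggregation resolutions (1–200 km style ladder) finds
   the finest resolution at which the occurrence pattern is no more
   autocorrelated than a random reference with ten times as many
   points.
4. **Thinning** (`thin_replicates()`): one point per selected-resolution
   cell per replicate, drawing replicates until every record has been
   used at least once (coupon-collector stopping rule); a deterministic
   cycling mode is available.
5. **Pseudo-absences** (`generate_random()`, `generate_weighted()`):
   four per presence, drawn without replacement over valid unoccupied
   cells — uniformly ("Random Pts") or proportional to the effort
   surface ("Weighted Pts") so the background inherits the presences'
   sampling bias.
6. **Model fitting** (`fit_glm()`, `tune_fit_brt()`,
   `tune_fit_maxent()`): three algorithm families behind one
   prediction/response-curve contract.
7. **Model selection** (`two_phase_select()`): AICc-ranked candidate
   sets, climatic and nonclimatic groups first, then exhaustive subsets
   of the pooled winners.
8. **Evaluation** (`cross_validate()`, `out_of_region()`): stratified
   5-fold cross-validation (80/20 per fold) and leave-one-region-out
   transferability, scored with AUC and Cohen's Kappa at the
   max(sensitivity + specificity) threshold.
9. **Interpretation** (`covariate_importance()`,
   `expert_weighted_score()`): algorithm-specific importance plus an
   expert-rubric weighting of response curves.
10. **Ensemble** (`build_ensemble()`, `project_ensemble()`): member
    maps averaged with weights proportional to cross-validated Kappa.

## Models and their assumptions

**GLM.** Logistic regression with linear + quadratic terms for
continuous covariates and dummy coding for categorical ones, no
interactions. Quadratic terms allow unimodal responses (an ecological
optimum) while remaining a convex estimation problem. Continuous
covariates are z-scored before expansion purely for IRLS conditioning;
the standardization constants are stored in the model, so predictions
are identical to a raw-scale fit.

**BRT.** Gradient-boosted trees with Bernoulli deviance loss (xgboost
backend). The tuning protocol searches tree counts, learning rates and
tree complexities by stratified k-fold CV; because boosting is
sequential, the CV deviance of *every* tree count on the grid is read
from a single run per (rate, complexity) pair. Selection is
lexicographic — smallest CV deviance, then fewest trees, then lowest
complexity, then lowest rate — favouring the most parsimonious of
equally skilled settings. The default grid (trees 100–2,000 by 100,
rates 0.001/0.005/0.01, complexities 1–3) is sized for desk-scale data;
`brt_grid_full()` provides the historical full lattice (trees to
10,000, rates 1e-4–1e-2, complexities 1–5). The published rate list for
that protocol prints one value twice; we use the de-duplicated set.

**MaxEnt-style model.** Maximum-entropy presence–background estimation
is mathematically equivalent to an L1-penalized logistic regression on
an expanded feature basis, and that is how it is implemented here
(glmnet backend): linear, quadratic, pairwise-product, forward and
reverse hinge, threshold, and categorical-indicator features, each
scaled to [0, 1] over the training rows. Hinge/threshold knots sit at
10 interior training quantiles per covariate. The single regularization
multiplier is selected from 0.2–5 in steps of 0.2 by 5-fold
cross-validated held-out log-likelihood; "multiplier m" scales a
reference penalty set two decades below the smallest penalty that zeros
every weight, so the grid spans visibly-underfit to visibly-overfit
solutions. The phrase "maximized from a combination of values" in the
source protocol is ambiguous; we read it as CV-based selection over the
stated interval.

**AICc across algorithms.** `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`
needs a parameter count `k`: exact coefficient count for the GLM,
number of nonzero feature weights (+ intercept) for the MaxEnt-style
model, and `covariates + 1` as an effective-parameter proxy for BRT.
The BRT proxy is flagged approximate in reports; candidate selection is
normally run with the GLM, where `k` is exact.

## Skill metrics

AUC uses the rank (Mann–Whitney) formulation with ties counted 1/2, so
it is invariant under strictly monotone rescaling of scores. Kappa is
computed at the threshold maximizing sensitivity + specificity
(Youden's J), scanning every distinct score value and breaking ties
toward the lower threshold. Out-of-region validation evaluates only
regions holding at least 25 presence records (presences only — the
pseudo-absences do not count toward eligibility); models are not
re-tuned per held-out region by default — the full-fit hyperparameters
are reused, which is cheaper and matches how transferability is used in
practice. Passing a tuning fitter to `out_of_region()` re-tunes if
wanted. Reported "fair skill" counts use the conventional AUC > 0.7 and
Kappa > 0.4 vocabulary; these are reporting constants, never inputs to
fitting.

## Covariate importance

* **GLM**: permute one covariate column, recompute predictions, and
  take the absolute paired t statistic of the per-row *fit* change
  (Bernoulli log-likelihood contribution before minus after), averaged
  over 10 permutations. We pair likelihood contributions rather than
  raw predictions because prediction differences are mean-zero by
  permutation symmetry — their paired t statistic would hover near zero
  for informative and uninformative covariates alike.
* **BRT**: per covariate, the sum of squared loss improvements (gain)
  over all splits on it, averaged over trees; one-hot columns fold back
  into their parent covariate.
* **MaxEnt-style**: the drop in training AUC after replacing the
  covariate with values drawn uniformly across its training min–max
  (uniform resampling, not permutation, to honour "across its range"),
  averaged over 10 draws and floored at zero.

Raw importances are standardized to sum to 100 within a model
(rank-preserving); standardization happens within replicate, then
averages across replicates. The expert rubric (integer scores 0–3 per
response curve, supplied as YAML) combines with standardized importance
as `mean(rubric_k * importance_k)`.

## The synthetic study system

`simulate_study()` builds the conditions every test runs under:

* **Covariates**: stationary Gaussian random fields — white noise
  smoothed with a Gaussian kernel whose standard deviation is half the
  requested correlation range — standardized to mean 0, sd 1, plus one
  categorical layer from thresholding an extra field into 4
  equal-frequency classes. Default: 64 x 64 grid of 1-km cells,
  correlation range 10 cells. The simple smoothing model is adequate
  for pipeline testing; it is not a geostatistical fit to any real
  landscape.
* **Virtual species**: responses combine additively on the logit scale —
  two unimodal (Gaussian) curves, one monotone (logistic) curve, one
  categorical effect — echoing the temperature / precipitation /
  distance-to-resource / land-class mix typical of vertebrate niche
  models. The intercept (−5) puts landscape prevalence near 0.65, i.e.
  a species occupying roughly two-thirds of the landscape, the
  situation this workflow targets; early drafts with higher intercepts
  produced degenerate near-one prevalence with no presence/absence
  contrast.
* **Sampling scenarios**: `"expert"` effort concentrates in a few
  clustered hotspots; `"citizen"` effort follows two broad corridors
  over a diffuse background. Records are drawn per cell with
  probability proportional to effort x suitability x detection, with
  replacement (repeat visits), jittered uniformly within the cell.
* **Regions**: a Voronoi partition of the grid around random seed
  cells — contiguous, exhaustive, non-overlapping.

What the generator does **not** emulate: detection covariates,
temporal dynamics of invasion, spatially correlated *errors* in
coordinates, and real covariate cross-correlations. Passing tests
therefore demonstrate that the machinery is correct and well
calibrated under known truth — not that any particular real dataset
meets the workflow's assumptions.

## Numerical choices

* Cell geometry is half-open: a point on a shared edge belongs to
  exactly one cell (right/bottom edges fall into the next cell; the
  grid's own top edge belongs to row 1).
* Rasters travel as ESRI ASCII grids — a plain-text, georeferenced,
  single-band format readable everywhere; CRS labels ride along in
  memory (planar metric coordinates are assumed throughout; no
  reprojection).
* The kernel density surface renormalizes to sum exactly to the point
  count after edge truncation; default bandwidth 5 cells, recorded on
  the result.
* Moran's I uses row-standardized inverse-distance weights with a
  cutoff of 3 block widths by default (rook contiguity available); the
  z-score uses the normality-assumption variance. For full-grid block
  lattices the weight matrix is built sparsely from neighbour offsets,
  so fine resolutions stay tractable.
* The resolution scan compares the occurrence pattern's I against the
  empirical distribution of I over 19 random reference point sets (10x
  the occurrence count each) and admits a resolution when the
  occurrence value is not significantly *above* the reference
  (one-sided, alpha = 0.05). One-sided because a pattern *less*
  autocorrelated than random needs no coarsening; partial edge blocks
  shift occurrence and reference I alike, which the reference
  comparison absorbs.
* Ripley's L uses the edge-corrected estimator of the `spatial`
  package on a rectangular window, with a pointwise min/max envelope
  from 99 CSR simulations.
* Pseudo-absence draws are without replacement at cell level (one
  point per cell), respecting the later one-point-per-cell thinning;
  occurrence-occupied cells are excluded so no cell carries both
  labels.
* Thinning replicates pair occurrence replicate k with pseudo-absence
  replicate k; if the two stopping rules produce different counts, the
  shorter list recycles cyclically.
* GLM convergence: IRLS to epsilon 1e-10, max 100 iterations;
  non-convergence is an error, fitted probabilities of 0/1 raise a
  separation warning.
* All boosting runs use a single thread, making results bit-reproducible
  under a fixed seed; `run_pipeline()` derives every stage seed from
  the single configured seed, and identical configurations reproduce
  evaluation tables and ensemble rasters byte for byte.

## Problem sizes

The test-suite and acceptance-script problem sizes are chosen as the
smallest systems on which each property is statistically decidable:
64 x 64 (occasionally 48 x 48) landscapes with 150–300 records per
source for pipeline-level properties; n = 2,000 training rows on a
128 x 128 landscape for niche-recovery checks; n = 5,000 for
coefficient recovery (20 seeds); n = 3,000 for selection consistency;
200 random instances (n <= 500) for metric-oracle equivalence. The
reduced BRT grid is the default at these sizes; conclusions about the
tuning *protocol* (CV, lexicographic selection) do not depend on the
grid's extent.

## Known limitations

* The MaxEnt-style model is the penalized-logistic equivalence, not the
  reference Java implementation; feature construction and the
  regularization path match in spirit (and satisfy the same contracts)
  but coefficient values are not comparable one-to-one.
* BRT's AICc uses an effective-parameter proxy; rankings that hinge on
  small AICc differences between BRT candidates should be treated with
  caution.
* Out-of-region skill on strongly autocorrelated landscapes is
  pessimistic by construction (the held-out region is environmentally
  novel); this mirrors the transferability literature rather than a
  defect of the implementation.
* The expert rubric is an input artifact: the package reproduces the
  arithmetic of expert scoring, not the judgement.
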