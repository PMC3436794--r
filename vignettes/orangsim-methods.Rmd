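---
title: "Methods: hurdle habitat models coupled to land-cover and climate scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hurdle habitat models coupled to land-cover and climate scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orangsim` projects the spatial abundance of a forest-dependent primate
under joint forest-management and climate scenarios. This vignette explains
the models, their assumptions, the tunable parameters, and the design
decisions taken where several defensible choices existed. Everything here
describes what the code does; no empirical claim is made beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The hurdle species distribution model

Gridded aerial nest counts are dominated by zeros, for two distinct
reasons: habitat may be unsuitable (a structural zero), or the habitat is
suitable but no nest was present at that density and survey effort. The
package therefore models two processes:

* a **binomial part** for presence/absence of nests in a cell, and
* a **Poisson part** for the mean nest count *conditional on presence*,
  fitted only on presence cells. Because the response is the average of
  repeat surveys it is real-valued; the Poisson deviance
  `2[y log(y/mu) - (y - mu)]` (with `y log(y/mu) := 0` at `y = 0`) is used
  in its quasi-likelihood reading.

Both parts are boosted regression trees — stagewise gradient boosting of
shallow trees — with four governing parameters: learning rate `lr`
(shrinkage per tree), tree complexity `tc` (interaction depth), bag
fraction `bf` (subsampling per boosting step, default 0.7) and the number
of trees `nt`. The ensembles are fitted with `xgboost`, which implements
the same algorithm family as the classical BRT toolchain.

**Tree-count selection.** For each candidate `(lr, tc)`, one staged fit per
cross-validation fold is evaluated on the held-out fold at every `nt` on a
grid (default `seq(10, nt_max, 25)`), giving the mean held-out deviance
curve `D_cv(nt)` and its fold-to-fold standard error. The component is
refit on all data at the argmin. The full-scale search space is
`lr ∈ {0.01, 0.005, 0.001}`, `tc ∈ {1, 2, 3}`, `nt` up to 15000; the
package's `hurdle_fit_config()` defaults cap `nt_max` at 1500 as a
desk-scale working grid, and the tests pair that reduced tree budget with a
larger learning rate so that the effective shrinkage budget `lr × nt`
matches the full-scale search (halving `lr` and doubling `nt` are
near-equivalent in gradient boosting).

**Simplification.** Starting from the saturated model, the predictor with
the lowest relative influence is dropped and the component refit; the loop
stops when `D_cv(simplified) − D_cv(saturated)` exceeds the saturated
model's cross-validation standard error. This is applied to the binomial
part, the Poisson part, and both; the variant with the lowest summed
component `D_cv` is kept, so an all-signal model survives simplification
unchanged. Summing the two components' `D_cv` is our documented choice of
a single comparison scalar; the per-component values are always reported
alongside.

**Pseudoabsences and thresholding.** Aerial surveys concentrate on forest
reserves, so unsurveyed cells outside reserves are sampled uniformly as
pseudoabsences (presence 0, no abundance information; they enter the
binomial part only). How many to draw is genuinely open; the package
exposes it as a free parameter rather than fixing a ratio. The fitted
presence threshold is the MaxSSS rule — the cut-off maximizing sensitivity
plus specificity, with ties broken toward the smallest threshold — which is
insensitive to the prevalence inflation pseudoabsences cause. Kappa is
reported at the mean of five standard thresholding rules (fixed 0.5,
observed prevalence, mean predicted probability, max-Kappa, MaxSSS): the
specific five-rule set is our documented choice among common practice.

**Cross-validation folds** are random partitions, stratified by presence
for the binomial part (stabilizing `D_cv` when prevalence is moderate),
with the seed recorded in the configuration.

**Spatial autocorrelation diagnostics.** Global and local Moran's I with
row-standardized contiguity weights justify the aggregation scale; queen
(8-neighbour) contiguity is the default with rook available, since
published grid analyses use either. With row-standardized weights the
global statistic equals the unweighted mean of the local ones, which the
tests exploit as an internal consistency check, alongside a brute-force
double-sum oracle.

## The land-cover change simulator

Two observed land-cover epochs (interval `T` years, strictly protected
areas excluded from estimation) give an interval transition matrix by
row-normalized cross-tabulation. The **annual** matrix is its `1/T` matrix
root via eigendecomposition; tiny negative entries that the root can
produce are clipped to zero and rows renormalized. This annualization is
our documented choice — the root is not guaranteed to exist for every
stochastic matrix, but for near-diagonal land-cover matrices it does, and a
round-trip test (`annual^T ≈ interval`) guards it.

**Which cells change** is decided by a vulnerability map: a random-forest
classifier predicts the current class from static spatial predictors, and
its per-cell class-membership probabilities define vulnerability (largest
probability of any class other than the predicted one) and the target
class (the runner-up; ties break toward the earlier class in the legend).
Each year, for each source class, the expected movers to each destination
(annual rate × class count, integerized by largest-remainder rounding so
destination totals conserve) are taken from the most vulnerable cells
whose target matches the destination, topping up from the next most
vulnerable cells regardless of target.

**Forest reserves** are treated separately, as harvest rather than
conversion: a constant annual quota — the reserve deforestation rate
applied once to the initial non-SFM reserve forest area, then held fixed,
independent of remaining forest — consumes the most vulnerable forest
cells, working through reserves in decreasing order of the mean
vulnerability of their remaining forest. The processing order is
recomputed every year from the current state; the alternative (a fixed
order from the initial state) is equally consistent with a sequential
reading, and recomputation is the choice we document. Harvested cells
become degraded and revert to forest exactly 60 years later
(`regen_years`, configurable); a single forest class is used for primary
and regrown forest rather than a distinct regrowth class. Reserves under
SFM are never harvested. Strictly protected areas never transition at all,
mirroring their exclusion from rate estimation.

## Climate projection

Scenario anomalies are epoch-indexed rasters: additive °C for temperature,
multiplicative per cent for wet-season (Oct–Mar) and dry-season (Apr–Sep)
precipitation, with the first epoch carrying no change. Between epochs the
deltas are interpolated linearly in time — the interpolation between
anomaly epochs is not dictated by the source maps, and linear is the
documented decision — and applied to the baseline climatology. Projections
never extrapolate beyond the last epoch. Cells whose projected climate
leaves the observed range are flagged (with per-variable exceedance);
model predictions in novel cells are extrapolations and are reported with
the novelty mask rather than clamped.

## From nest counts to population

Predicted cell counts convert to the per-km transect index `A` by dividing
by the transect length one survey line contributes to a cell — the cell
side length by default, configurable, since a gridded count has no unique
per-km normalization. Density follows the allometric conversion
`D = exp(4.730 + 0.980 ln A)/(p r t)` with `p = 0.9`, `r = 1.084`/day and
`t = 286.3` days, extended continuously with `D(0) = 0`; abundance is
density × cell area. The presence threshold is held at its fitted value
across all projection years (no re-thresholding rule exists), and no
dispersal constraint is imposed: any cell crossing the threshold is
immediately occupied. Four named scenarios pair the two SFM policies
(current reserves only vs all reserves) with the two climate pathways
(unabated "Ref"-like vs stabilization "Pol"-like).

## The synthetic landscape

The generator emulates the statistical structure the analysis assumes, not
any real geography: smooth terrain from Gaussian-random-field noise
(fixed-width separable kernel, width in cells configurable), Euclidean
distances to randomly placed roads, rivers and settlements, rectangular
reserve blocks with an SFM subset and one strictly protected block,
deterministic initial land cover from terrain and features, and climate
fields with an elevation lapse. True response surfaces are logistic
(presence) and log-linear (expected count) in **z-scored** predictors, so
coefficient magnitudes are scale-free; optional product terms inject true
interactions. Surveys are straight north–south transects at a configurable
spacing (5 km main-survey-like, 3 km validation-like); each surveyed cell
yields a Bernoulli presence draw times a Poisson count, per visit, and a
configurable fraction of transects is restricted to reserves to reproduce
survey bias. Counts are generated per cell; the per-km conversion is
applied downstream.

Defaults describe the study conditions: a five-class legend dominated by
forest, ~1.2% of forest converted per year in the truth matrix, about a
third of cells in reserves with a fifth of reserves under SFM, 2.5 km
cells, and end-of-century state-mean temperature deltas of +2.5 °C
(Ref-like) and +1.2 °C (Pol-like) with near-stable precipitation.

What the generator does **not** emulate: real fragmentation geometry,
correlated classification error between epochs, flight-path curvature,
observer error in nest detection, and hunting legacies. Passing tests
therefore demonstrate that the machinery recovers what it assumes, not
that the assumptions hold for any particular real dataset.

## The surface-recovery experiment

The acceptance-level recovery check asks whether the fitted hurdle model
reproduces the known truth. Its design: 45 × 45 landscapes (2025 cells)
under the strong-signal defaults, an **unbiased full-coverage survey**
(no reserve restriction, no pseudoabsences) over ten seeds, fitting at
`lr = 0.1`, `tc = 2`, `nt ∈ seq(10, 1500, 25)`, 10 folds. The unbiased
design is deliberate: pseudoabsences exist to patch survey bias and do so
by *mislabelling* possibly suitable cells as absences, so a recovery
experiment run through them would confound estimator error with the cost
of that correction. Recovery is scored on cells absent from the training
data: the binomial part's rank AUC against true habitat suitability
(true presence probability ≥ 0.5), the Spearman correlation between the
composed hurdle prediction and the true expected abundance surface, and
the Poisson part's deviance explained. Scoring discrimination against a
single Bernoulli realization instead would bound AUC by the draw's own
noise (the true probabilities themselves score ≈0.87–0.91 against their
own draws) and would measure the generator, not the estimator. The
biased-survey-plus-pseudoabsence path is exercised end to end by the
pipeline tests and the demonstration run.

## Numerical choices and degenerate inputs

* Probabilities are clamped to `[1e-12, 1 − 1e-12]` inside the binomial
  deviance; Poisson means are floored at `1e-12`.
* Moran's I on a constant field is an error, not `NaN`; transition
  estimation for a class absent at the first epoch yields an identity row
  with a warning.
* Ties: MaxSSS takes the smallest maximizing threshold; vulnerability
  target classes and predicted classes break ties toward the earlier
  legend class; simplification drops the earlier column among
  equal-influence predictors.
* Integerization of expected movers uses floors plus largest remainders so
  destination totals match the rounded expected outflow exactly; cell
  counts are conserved at every step by construction and asserted in
  tests.
* All stage seeds derive from one master seed by fixed offsets; the
  pipeline manifest records per-file MD5 hashes, and a rerun with the same
  configuration reproduces them bit for bit.
* Rasters are plain-text ESRI ASCII grids written at full double
  precision (`%.17g`), the package's native exchange format; row 1 is the
  grid's north edge.

## Problem sizes

The shipped configurations are sized for a single CPU: the demonstration
pipeline uses a 32 × 32 grid, a one-point `(lr, tc)` search with trees up
to 750 and 5 folds, 90 projected years and all four scenarios; the
recovery experiment uses 45 × 45 grids and ten seeds; module tests use
grids from 4 × 4 to 50 × 50. All are the package's own choices of working
scale, and every size is a config argument — the same code runs the full
classical search (`nt` to 15000, 3 × 3 parameter grid, 10 folds) by
changing `hurdle_fit_config()`.

## Known limitations

* The Markov simulator has no fire, drought or economic feedback; harvest
  is constant by design, and unprotected conversion is permanent.
* The hurdle model is static: no dispersal limits, hunting pressure or
  demographic dynamics; projected occupancy responds instantaneously to
  habitat and climate.
* The matrix root may not exist for strongly mixing interval matrices;
  the clip-and-renormalize repair is validated only near the
  land-cover-like regime.
* Predictions in climatically novel cells are extrapolations; the package
  reports the novelty mask but does not constrain the response surfaces.
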