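---
title: "Methods: coupling habitat suitability models with a stage-structured metapopulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling habitat suitability models with a stage-structured metapopulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapva)
```

## The problem

Wild-harvested plants such as the Natal lily (*Clivia miniata*), a heavily
traded medicinal species of southern Africa, face three pressures at once:
a shifting climate, conversion of natural land cover, and direct harvesting.
`metapva` implements a population viability analysis that treats these
pressures jointly: a habitat suitability model (SDM) projects where the
species can live; the suitability surface is converted into habitat patches
with carrying capacities; and a stochastic, stage-structured metapopulation
simulator projects abundance under scenario forcing. Because the real
climate, occurrence, land-cover and demographic inputs of any particular
study are large external datasets, the package ships a synthetic-data module
that generates all inputs with known ground truth, making every stage of the
pipeline testable end to end.

## Synthetic data: what it emulates and what it does not

`gen_landscape()` builds a square grid carrying a smooth ground-truth
suitability surface and predictor layers. Three gradients are available:

* `"linear"` — suitability rises monotonically west to east through a
  logistic link on a temperature-like predictor (`bio1`, 14–22 °C);
* `"hill"` — a cool-adapted montane species: `bio1` is coolest at the
  central peak and the (decreasing) logistic link confines suitability to a
  compact core occupying roughly a tenth of the domain. This landscape is
  the default study condition because it gives the SDM a strong,
  recoverable signal (out-of-fold AUC well above 0.9 at 200 presences) and
  because warming contracts the suitable core, which is what the
  climate-change scenarios need to exercise;
* `"flat"` — constant suitability, used for sampling-distribution tests.

Presences are drawn with probability proportional to suitability (intensity
sampling), background points uniformly over the remaining cells. This is a
deliberate simplification of target-group background construction used with
real occurrence archives; the generator makes no attempt to reproduce
spatial sampling bias, record duplication, or coordinate error in real
archives, so a model that passes here may still struggle on biased real
data.

`gen_stage_counts()` projects known initial stage counts (juvenile,
subadult, adult) through a known projection matrix and records counts,
stage-to-stage transitions, per-stage recruits, and deaths. With
`observation_noise_cv = 0` the table records exact expected counts
(real-valued). We chose expectations over integer rounding deliberately:
the noise-free table is then *exactly* consistent with the generating
matrix, so the rate fitter must recover it to numerical precision — a sharp
round-trip oracle. Rounded integer counts are produced as soon as
observation noise is requested, which is the realistic regime.

`gen_gcm_series()` emulates coarse climate-model output by block-aggregating
a fine monthly baseline and adding a linear trend plus interannual noise;
`gen_landcover_mask()` produces scattered or blob-clustered binary masks
with an exact unsuitable-cell count.

## The suitability model and its evaluation

Three algorithms sit behind one interface (`fit_sdm()`): a binomial GLM, a
ridge-regularized logistic regression on linear + quadratic features (a
deliberate approximation to maxent-style exponential models on
presence/background data — the package does not reimplement maxent's
feature classes or regularization path), and a probability random forest.
Fivefold evaluation (`kfold_evaluate()`) assigns presences and background
points to folds by stratified random split — the split rule is a package
choice; fold metrics are sensitivity, specificity, TSS
(= sensitivity + specificity − 1) and rank-based (Mann–Whitney) AUC with
ties counted one half. The binarization threshold is "no omission": the
minimum predicted score among *training* presences, so training sensitivity
is 1 by construction while held-out presences may still be omitted.

Member maps are combined by `ensemble_weighted_mean()` with weights
proportional to raw AUC. Weighting by AUC − 0.5 would punish near-random
members harder; raw AUC is the simplest defensible reading of
performance-weighted averaging and is what the function implements (callers
can pass any weights). The land-cover mask multiplies the ensemble map, so
masked cells are exactly zero.

## Climate forcing

Delta-change ("pattern") downscaling: coarse anomalies — additive for
temperature, multiplicative for precipitation with the reference month
floored at 0.1 mm to avoid ratio blow-ups — are applied per containing
coarse cell to the fine baseline (nearest-coarse-cell assignment, no
interpolation). Bioclimatic variables use the standard monthly definitions
(annual mean temperature, seasonality as SD × 100, warmest-month
temperature, annual precipitation, wettest/driest month), configurable as a
subset.

Suitability is not updated yearly in the simulator. `temporal_schedule()`
updates the map every 5 years using a 10-year running mean; we align the
window *trailing* (ending at the labelled year) so an update never uses
future climate. Over a 30-year horizon this yields 7 scheduled maps
(the 2020s through 2050s pattern).

## Demography

Vital rates come from stage-count census tables via `error_minimize()`:
constrained least squares over the 9 free rates (three-stage matrix with
reproduction pooled into the juvenile row of the subadult/adult columns),
minimizing squared discrepancies of both year-to-year stage counts and
recorded per-entry transition/recruit counts, subject to nonnegativity and
per-stage survival sums ≤ 1. Both discrepancy terms matter: with only
count-to-count terms a two-year census would be underdetermined (3 equations,
9 unknowns); the per-entry terms make it exactly determined, and on
noise-free tables the direct ratio estimates already have zero objective, so
recovery is exact. The optimizer is `nlminb` from those ratio starts.

Uncertainty is captured by a nonparametric bootstrap over census
transition-years (`build_matrix_pool()`); the pool's first member is always
the full-table point estimate. Percentile matrices (2.5/50/97.5 by
dominant eigenvalue) use the nearest-rank definition so a selected matrix is
always an actual pool member. The stable stage distribution is the Perron
eigenvector; for reducible matrices (e.g. the identity), where it is not
unique, the documented fallback is uniform.

## Patches, carrying capacity, land cover

`delineate_patches()` groups cells at or above a suitability threshold into
connected components under a centre-to-centre distance rule (default 5 km on
a 1-km grid), treating dispersal implicitly: clusters nearer than the
threshold are one population. Distances are Euclidean in projected km — at
landscape scale no great-circle correction is warranted.

Carrying capacity scales with habitat quality and extent:
`K = round(density × Σ suitability × cell area)`. The density scalar (how
many individuals one unit of summed suitability supports per km²) is not
derivable from first principles and is a required configuration value; the
bundled configuration uses 100, which puts a 24×24-km synthetic landscape
in the thousands of individuals — a realistic scale for a locally abundant
understorey herb. Initial abundances apportion K across stages by the
stable stage distribution (largest-remainder rounding). When the habitat
map updates, K is recomputed on the patch's member cells; patch geometry is
kept fixed from initialization (the 5-yearly maps change quality far more
than topology at these scales), and a maximal-overlap matcher
(`match_patches()`) is provided for re-delineated maps — splits keep the id
of the larger fragment, merges take the lower id, unmatched patches get
K = 0 with a warning. Abundance is *not* truncated when K drops; the
ceiling rule enforces the new K at the next projection step.

Land-cover change: "intensification" freezes the mask (conversion stops);
"expansion" converts round(rate × suitable cells) per year (default 1%/yr),
drawn uniformly among suitable cells within one cell (queen's move) of an
already-unsuitable cell — "proximity" needs a radius and one cell is the
most conservative choice; if the frontier is smaller than the quota the
remainder falls to the nearest-frontier cells.

## The simulator

Environmental stochasticity multiplies vital rates by lognormal mean-1
deviates: CV 0.20 for reproduction, 0.10 for survival/transitions (the
defaults follow magnitudes used in published viability analyses of
southern-African vegetation). Within each stage, the deviate of the
largest survival rate is negatively correlated (construction correlation
−0.7 on the underlying normals) with the deviates of that stage's other
survival rates, which limits truncation when survival sums approach 1;
any remaining excess is truncated by scaling the column back to sum 1.
Deviates are drawn independently per population and year — no spatial
correlation is imposed.

The yearly event order is: scheduled K update → projection → ceiling →
harvest. Projection uses expected values with unbiased stochastic rounding
to integers by default (`rounding = "round"` and `"none"` give the
deterministic limits; a binomial/Poisson demographic-stochasticity mode
exists behind a flag and is off by default). The ceiling rule scales all
stages proportionally (largest remainder) so the total never exceeds K
after application.

Harvest: a fixed quota (default 5) per population every second year
(events fire on even simulation years), only when the population total is
at least 50 — small populations are assumed harder to find. `"JUV"`
removes juveniles only, capped by availability; `"ALL"` removes the quota
across stages proportionally to abundance, largest-remainder rounded with
ties broken juvenile → subadult → adult. Established metapopulation
engines do not document whether harvest is applied before or after density
dependence within a year; the order here is fixed and stated, and the
directional conclusions (harvesting all stages depresses abundance at
least as much as juvenile-only extraction) are insensitive to it in our
tests.

Summaries report nearest-rank percentiles (2.5/50/97.5) of total abundance
as a percentage of initial conditions, cumulative quasi-extinction
probability (default threshold: 10 individuals metapopulation-wide — the
literature reports "high extinction risk" without a fixed threshold, so
this is a configurable package default), and per-decade changes relative to
a baseline scenario. `classify_interaction()` compares the combined-
pressure effect with the sum of single-pressure effects: larger in
magnitude is synergistic, equal (within 1 percentage point) additive,
smaller antagonistic — and whenever the uncertainty intervals of the
combined effect and the sum overlap, the verdict is "indeterminate", the
honest answer when replicate spread swamps the difference.

## Numerical choices and problem sizes

All randomness flows from one root seed through named substreams
(`derive_seed()`), so pipelines rerun bit-identically and scenarios can be
paired replicate-by-replicate. Rasters serialize to a plain-text grid
format at `%.17g` precision, which round-trips IEEE doubles exactly.

The test suite exercises the contracts at sizes a laptop handles in
minutes: grids up to 50×50, 100 bootstrap tables for the λ-recovery check
(median |λ̂ − λ| ≤ 0.03 at 10% observation noise), 200 random grids against
a brute-force connected-components oracle, 500–1000 replicates for the
stochastic-consistency, harvest and scenario-ordering properties, and a
bundled 24×24 smoke configuration (50 replicates, 10 years) for the full
pipeline. The published studies this methodology serves run 10,000
replicates over 30 years; the simulator takes those settings unchanged
through `sim_config()`.

## Known limitations

* The maxent-like member is a regularized logistic approximation, not
  maxent; transfers of fitted models far outside the training predictor
  range inherit the usual extrapolation hazards.
* Dispersal is implicit in the patch-delineation distance; there is no
  explicit inter-patch dispersal kernel, no genetics, and no Allee effect.
* The synthetic generators produce smooth, stationary landscapes and
  unbiased observation noise; conclusions about real, spatially biased
  occurrence data or non-stationary land-cover trends require the real
  inputs.
* Suitable-area and abundance trajectories from the bundled synthetic
  conditions characterize the machinery, not any particular species or
  region.
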