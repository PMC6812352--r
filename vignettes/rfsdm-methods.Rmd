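---
title: "Presence-only species distribution modelling with random forests: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only species distribution modelling with random forests: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfsdm)
```

## The problem

Most occurrence data — herbarium records, atlases, volunteer observations —
tell us only where a species *was seen*, never where it is reliably absent.
Random forests, however, need both classes. `rfsdm` implements a complete,
reproducible procedure for building presence/pseudo-absence random-forest
species distribution models (SDMs): it manufactures defensible absences,
keeps the spatial structure of the data from inflating accuracy estimates,
turns continuous suitability into presence/absence maps with objective
thresholds, and combines many partial models into one ensemble map.

Every stage is exercisable on synthetic data with a known truth surface, so
the package's claims about itself are testable end to end.

## The modelling procedure

### Collinearity pruning

Climatic predictors are strongly inter-correlated, which destabilises
variable importance and hampers transfer to new climates. Before modelling,
the pairwise Pearson correlation matrix of the stack (over jointly valid
cells) is pruned greedily: while any retained pair has `|r|` above the
cutoff (default 0.8), the worst pair is located and the member with the
larger mean absolute correlation to everything else is dropped, ties going
to the later-listed layer. The rule is deterministic for a fixed layer
order, idempotent, and guarantees no surviving pair above the cutoff.
Absolute correlation is used deliberately — strong negative collinearity is
as harmful as positive. The 0.8 default is a field convention rather than a
statistical derivation, which is also why the cutoff is a visible parameter.

### Pseudo-absences

Two candidate generators are provided:

* **Geographic exclusion** (`geographic_candidates()`): a valid cell is a
  candidate when its center lies at least `min_degrees` (default 2) from the
  nearest presence center. Distance is Euclidean in degree space between
  cell centers by default; a Chebyshev variant (`max(|dlon|, |dlat|)`) is
  offered because "two degrees in latitude or longitude" honestly admits
  both readings.
* **Surface range envelope** (`sre_candidates()`): the envelope is the
  closed per-layer `[min, max]` of predictor values at presences; a cell
  is a candidate only when at least one layer falls *strictly* outside.
  A boundary value is inside the envelope — the envelope defines
  suitability, so eligibility requires genuine exceedance. The SRE route
  shares its piecewise-constant nature with trees, so it should not be used
  when the goal is to compare tree-based algorithms against each other; it
  is provided for mapping use.

From the candidates an initial sample **PA1** of 20,000 cells (default) is
drawn uniformly without replacement. When fewer candidates exist, all are
taken and a warning is raised. Replicate PA1 draws are independent and may
overlap.

### Spatial blocks and folds

Spatial autocorrelation lets models look better than they are: nearby test
points are quasi-duplicates of training points. Presences are split into
four geographically disjoint blocks — at the midpoint of the presence
longitudinal *extent* (the dividing meridian), then each half at the
midpoint of its own latitudinal extent. Cells go west when `lon < meridian`
and north when `lat >= parallel`; the boundary rules are fixed so the
partition is a deterministic total function. Splitting on equal extent
rather than equal counts was an open reading; equal extent was chosen
because it matches the "same longitudinal range" description of the halves
and keeps blocks contiguous. The block count is fixed at four, for which
the six unordered training pairs give the fold plan; of the two held-out
blocks the lower id tests the model and the higher sets the threshold (a
flag swaps them — the assignment is genuinely unspecified, and six rather
than twelve sub-models per replicate pins down only the pair structure).

### Sub-model datasets

Per replicate and fold: `MCp` (training presences) are the two training
blocks' presences, matched 1:1 by `MCpa`, a simple random PA1 subsample.
The test presences `MVp` and threshold presences `TSp` get their absences
by **pairwise distance sampling**: each presence, in input order, is
matched to an unused PA1 cell whose distance to the nearest training
presence is within 33% of the presence's own, minimizing that gap. This
removes *spatial sorting bias* — otherwise test absences lie systematically
farther from the training data than test presences do, and discrimination
is overstated. Presences with no eligible candidate are dropped (and
counted) rather than matched loosely, preserving the exact 1:1 ratio that
the procedure mandates; the 0.33 tolerance is the matching method's own
convention. `MCpa` is drawn per fold (each fold has a different `|MCp|`);
the three absence sets of a fold are disjoint by construction. Matching
distances are great-circle (haversine) by default, with a degree-space
option for flat synthetic grids.

Seeds: replicate `r` draws PA1 with `seed + r`; fold `f` of replicate `r`
draws `MCpa` with `seed + 1000 r + f`; sub-model fits use
`seed + 10000 r + 100 f`. Every one of the 18 datasets and 36 fits is
independently reproducible, and all sampling restores the caller's RNG
state.

### CT and RT random forests

Both algorithms delegate the tree ensemble to the `randomForest` package
and own only the contract on top of it:

* **CT** (classification): the fraction of trees voting "presence" is read
  as a relative index of occurrence in `[0, 1]`, with granularity
  `1/n_trees`; presence and absence vote fractions sum to one.
* **RT** (regression): trees are fit to the 0/1 labels and averaged, which
  stays in `[0, 1]` automatically.

Defaults are the learner's own (500 trees, `sqrt(p)` features per split
for CT, `floor(p/3)` for RT) and are deliberately not tuned: tree-ensemble
SDMs are famously insensitive to these parameters, and a regression test
asserts that test AUC moves by less than 0.05 across 250–1000 trees on the
standard fixture.

### Evaluation metrics

Threshold-independent, for predictions \(p_i\) against observations
\(o_i \in \{0,1\}\) with prevalence \(\bar p\):

\[
\mathrm{RMSE} = \sqrt{\tfrac1n\sum_i (p_i-o_i)^2},\qquad
\mathrm{MAE} = \tfrac1n\sum_i |p_i-o_i|,
\]
\[
R^2 = 1 - \frac{\tfrac1n\sum_i (p_i-o_i)^2}{\bar p(1-\bar p)},\qquad
\mathrm{MXE} = -\tfrac1n\Big[\sum_{o_i=1}\ln p_i + \sum_{o_i=0}\ln(1-p_i)\Big].
\]

\(R^2\) is normalized by the error of the constant-prevalence predictor, so
a no-skill model scores 0 and the score is undefined (returned as `NA`, not
an error) for one-class samples. For MXE, predictions are clamped to
\([10^{-15}, 1-10^{-15}]\): CT vote fractions of exactly 0 or 1 would
otherwise yield infinite cross-entropy, and the clamp bound is far below
any attainable vote granularity.

The ROC AUC uses the Mann–Whitney form (probability a random presence
outranks a random absence, ties counted ½) — exact, not an integration
artefact. The areas under the sensitivity, specificity and accuracy curves
integrate those step functions of the threshold by the trapezoid rule over
the exhaustive candidate grid `{0} ∪ unique(p) ∪ {1}`. The classification
rule is fixed globally as `p >= t → presence` (ties to presence).

Threshold-dependent, from the confusion matrix: sensitivity, specificity,
overall accuracy (OA), `TSS = sensitivity + specificity − 1`, and Cohen's
Kappa with chance agreement
`p_e = [(TP+FN)(TP+FP) + (TN+FP)(TN+FN)]/n²`.

### Threshold selection

Eight methods (`select_threshold()`): the fixed default 0.5; the mean
predicted probability of the threshold-setting data (presences *and*
pseudo-absences — "the threshold-selecting data" is read as all of it);
predicted-prevalence-equals-observed; sensitivity = specificity; and the
four objective optimizers MaxOA, MinROCdist, MaxKappa, MaxTSS. All
data-driven methods optimize over the finite candidate grid — every
objective is a step function of `t`, so the grid is exhaustive and no
continuous search is needed — breaking ties toward the smallest threshold
(objectives equal within `1e-12` count as tied, so floating-point
evaluation order cannot split a mathematical tie). MaxTSS is the package
default, with MaxKappa, MaxOA and MinROCdist grouped alongside it as the
recommended objective methods; when sensitivity and specificity cross
exactly at a candidate, MaxTSS and Sens=Spec coincide. For Sens=Spec
without an exact crossing the nearest-`|sens−spec|` candidate is taken,
smallest-`t` on ties.

### Ensembles

Per replicate, the six sub-model suitability maps combine cellwise by
**maximum** — each sub-model was trained on only half the blocks, so the
ensemble trusts whichever sub-model is most confident, an assumption that
is honest only while all sub-models are acceptably accurate. An optional
accuracy gate (`accuracy_floor`) drops sub-models below a test-AUC floor
before ensembling, off by default. The final numeric map is the cellwise
**mean** of the three replicate maps. Binary maps: a replicate's complete
map is the cellwise OR of its six thresholded sub-models ("present in at
least one"), and the final map requires agreement of at least two of the
three replicates. Nodata propagates through every combination.

## The synthetic-data generator

`generate_stack()` builds layers as smoothed standard-normal noise
(separable moving-average of radius `round(smoothing)` cells, then
standardized), giving the spatial autocorrelation real climate fields
have; requested collinear pairs are reconstructed as
`r·layer_j + sqrt(1−r²)·independent`. `make_virtual_species()` defines truth
as a logistic surface `s = plogis(β₀ + Σ βⱼ xⱼ)` and samples presence cells
without replacement with probability proportional to `s`. A logistic truth
gives a known ranking, so discrimination (AUC, rank correlation) has an
unambiguous target.

Two fixture geometries are used throughout the tests and the acceptance
script, chosen once as realistic study conditions:

* **standard recovery fixture** — 60×60 cells of 0.5°, 3 layers,
  smoothing 3, coefficients (−1; 3, −2, 1.5), 300 presences: a desk-scale
  species with a clear but noisy climatic niche;
* **large candidate-pool fixture** — 300×300 cells of 0.2° (a continental,
  China-sized extent, matching the scale at which this workflow is used),
  smoothing 8, coefficients (−2; 5, −4, 3), 300 presences: a compact niche
  on a large grid, so the 2-degree exclusion leaves tens of thousands of
  candidate absences and the full PA1 of 20,000 can be drawn.

What the generator does *not* emulate: anisotropy and elevation structure
of real climate fields, observation bias (roads, collectors), dispersal
limitation, biotic interactions, and non-logistic (e.g. unimodal) species
responses. Passing the recovery tests therefore shows the machinery is
correct and the procedure coherent — not that any real species will be
predicted with Spearman ρ ≈ 0.95.

## Numerical and interface choices

* Grids are exchanged as ESRI ASCII grids (`.asc`), the plain-text raster
  format every GIS reads; layers must be pre-aligned (alignment is
  validated, never repaired — resampling and reprojection are out of
  scope).
* Cells use 1-based (row, col) with row 1 at the north edge; cell (r, c)
  covers `lon ∈ [left, right)`, `lat ∈ (bottom, top]`, so a point on a
  shared edge belongs to the south/east neighbour and point-in-cell is
  unambiguous.
* Degenerate inputs fail loudly and early: constant layers in the
  correlation, single-class training data, presences with zero spatial
  extent, empty candidate masks, PA1 smaller than a fold's training
  presences, and folds whose evaluation roles empty out after matching all
  raise errors naming the offending piece.
* The stagewise operations are R functions; the shipped CLI
  (`inst/cli/rfsdm.R`) wraps only the two end-to-end verbs, `fixtures` and
  `run`, because an R user composes the stages in R.
* Problem sizes in the test-suite were chosen so the whole suite and the
  acceptance script each complete in well under a minute of compute at
  desk scale: the full 36-sub-model, both-algorithm pipeline on the
  standard fixture takes roughly ten seconds.

## Known limitations

* Only the four-block geometry is implemented; choosing the block count
  from the residual autocorrelation range is not attempted.
* The max-combination ensemble inherits its stated assumption; with weak
  sub-models it overpredicts, and the accuracy gate is the only guard.
* Pseudo-absence generation offers no target-group or bias-surface
  options.
* CT and RT are ensembled separately and never averaged across algorithms;
  the run report annotates which algorithm won on discrimination (AUC) and
  on reliability (RMSE, R²) instead of silently choosing one.
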