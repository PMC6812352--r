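# rfsdm

Random-forest species distribution modelling (SDM) from presence-only data,
as a tested, reproducible R pipeline.

Occurrence data from collections and atlases record where a species *was
seen*, never where it is reliably absent — yet random forests need both
classes. `rfsdm` implements the full procedural framework for this
situation, for ecologists and biogeographers who model many species at
once:

1. **Collinearity pruning** of an aligned environmental raster stack:
   greedy elimination until no pair of predictors has Pearson `|r| > 0.8`.
2. **Pseudo-absence generation** by geographic exclusion (cells ≥ 2° from
   every presence) or by the surface range envelope (cells with at least
   one predictor strictly outside the presence min–max envelope), then a
   uniform sample **PA1** of 20,000 candidate absences.
3. **Spatial block cross-validation**: presences split into 4 geographic
   blocks (meridian, then parallels at extent midpoints); each of the 6
   block pairs trains a sub-model while the two held-out blocks test it
   and set its threshold. With 3 independent PA1 replicates this gives the
   18 sub-model datasets of the design, each trained 1:1
   presence:pseudo-absence, with test/threshold absences matched by
   pairwise distance sampling to remove spatial sorting bias.
4. **Two algorithms** per dataset: the classification forest's
   presence-vote fraction (CT) used as a relative index of occurrence, and
   the regression forest's averaged prediction (RT).
5. **Evaluation**: RMSE, MAE, R², mean cross-entropy, ROC AUC
   (Mann–Whitney), and areas under the sensitivity / specificity /
   accuracy vs-threshold curves; sensitivity, specificity, OA, Kappa and
   TSS = sensitivity + specificity − 1 at the chosen threshold.
6. **Objective thresholds**: eight methods (default 0.5, MeanProb,
   PredPrev=Obs, Sens=Spec, MaxOA, MinROCdist, MaxKappa, MaxTSS — the
   default), optimized exactly over the finite candidate grid.
7. **Ensemble maps**: per replicate the cellwise *maximum* of the six
   sub-model maps; the final numeric map is the *mean* of the three
   replicate maps. Binary: present if ≥ 1 of 6 sub-models says so, final
   if ≥ 2 of 3 replicates agree.

A synthetic-data module (`generate_stack()`, `make_virtual_species()`)
builds spatially autocorrelated predictor stacks and virtual species with a
known logistic truth surface `s = plogis(β₀ + Σ βⱼxⱼ)`, so the whole
pipeline is testable with no external data. Rasters are exchanged as
plain-text ESRI ASCII grids (`.asc`).

## Worked example

```r
library(rfsdm)

# a synthetic study region: 5 layers, one engineered collinear pair
st <- generate_stack(n_layers = 5, n_rows = 60, n_cols = 60, smoothing = 3,
                     collinear_pairs = list(c(1, 2, 0.95)), seed = 1)
vs <- make_virtual_species(st, c(-1, 3, 0, -2, 1.5, 0), 300, seed = 2)

run <- run_pipeline(st, vs$occurrences, sdm_config(seed = 3))
run
#> sdm_run: virtual - 36 sub-model(s), 4 predictor(s) kept
#>   mean test AUC CT = 0.968
#>   mean test AUC RT = 0.97

run$kept_layers
#> [1] "env_01" "env_03" "env_04" "env_05"

head(run$submodels[, c("replicate", "fold", "algorithm",
                       "auc_roc", "rmse", "threshold", "tss")], 4)
#>   replicate fold algorithm   auc_roc      rmse threshold       tss
#> 1         1    1        CT 0.9813850 0.2346857     0.480 0.8736842
#> 2         1    2        CT 0.9818445 0.2646834     0.322 0.8358209
#> 3         1    3        CT 0.9434071 0.3120283     0.274 0.6779661
#> 4         1    4        CT 0.9794536 0.2395260     0.394 0.8484848
```

The engineered duplicate of layer 1 (`env_02`, r ≈ 0.95) is pruned before
modelling, leaving four predictors. The 36 rows of `run$submodels` are the
18 sub-models × 2 algorithms: each row reports that sub-model's
threshold-independent metrics on its spatially separated test block, the
MaxTSS threshold chosen on its threshold-setting block, and the
threshold-dependent metrics at that threshold. Here both algorithms
discriminate well (mean test AUC ≈ 0.97 across sub-models);
`run$guidance` notes that RT won on discrimination and CT on reliability
for this species, the trade-off to weigh when picking an algorithm.
`run$ensembles$CT$numeric$final` is the ensemble suitability map (a
matrix-backed grid you can write with `write_asc_grid()`), and
`...$binary$final` the 2-of-3 consensus range map.

A thin command-line wrapper for the two end-to-end verbs lives at
`inst/cli/rfsdm.R`:

```sh
Rscript inst/cli/rfsdm.R fixtures --out demo --seed 1
Rscript inst/cli/rfsdm.R run --config demo/config.json --out demo/out
```

See `vignettes/rfsdm-methods.Rmd` for the full account of the model,
parameter defaults, numerical choices and limitations.

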