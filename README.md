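# forestNPP

Forest net primary productivity (NPP) analysis for mountain landscapes:
light-use-efficiency NPP estimation, stable/changing-forest change coding,
per-pixel trend and persistence mapping, and interpretable machine-learning
driver attribution — with a seeded synthetic study system so every stage is
testable against known ground truth.

## Who this is for

Carbon-cycle and remote-sensing ecologists who analyse annual NPP raster
time series (e.g. MODIS-scale products over a province) and want a
reproducible, tested implementation of the full chain from monthly NDVI
and climate to "which drivers control NPP, where, and with what
thresholds".

## The models

**CASA.** Monthly NPP is absorbed photosynthetically active radiation
times the actual light-use efficiency,

    NPP(x,t) = APAR(x,t) × ε(x,t),      ε = Tε1 · Tε2 · Wε · ε*

with APAR = SOL × FPAR × 0.5, FPAR the mean of the NDVI-linear and
simple-ratio estimates clipped to [0.001, 0.95], temperature stress
scalars Tε1 (quadratic in the optimum temperature) and Tε2 (two-sided
logistic around it), moisture stress Wε = 0.5 + 0.5·EET/PET (Thornthwaite
PET), and a per-class maximal efficiency ε* from an editable lookup table.
Annual NPP is the calendar-year sum.

**Change coding.** Land-cover transitions are encoded as C = 10A + B on a
single-digit remapped legend (forest subclasses 1–5); stable forest (SF)
holds one forest subclass in every year, changing forest (CF) is any
subclass shift or forest/non-forest transition.

**Trend and persistence.** Theil–Sen slope ρ = median over pairwise
slopes, Mann–Kendall S/Z/p with tie correction, a five-class trend map
(significant/slight × increase/decrease, plus "no change"), rescaled-range
Hurst exponents with the Anis–Lloyd expected-R/S small-sample correction
(anti-persistent < 0.5 < persistent), and a seven-class future-trend
superposition.

**Attribution.** Per-stratum random-forest regressions of multi-year mean
NPP on Pre, Tem, Srad, Slope, Ele, Asp, Ha, forest type and forest age
(70/30 split, Gaussian-process Bayesian hyperparameter tuning), decomposed
with *exact* tree-Shapley values and pairwise interaction values under
interventional conditioning (all 2^9 feature subsets enumerated in C++),
plus partial-dependence curves with density flags and automated threshold
extraction.

## Worked example

```r
library(forestNPP)

# a 48 x 48, 22-year synthetic study system with known truth
sys <- generateStudySystem(nrow = 48, ncol = 48, years = 2001:2022,
                           changeFraction = 0.3, seed = 11)

# CASA NPP from NDVI + climate, validated against the true NPP
est <- casaNpp(sys$ndvi, sys$landcover, sys$pre, sys$tem, sys$srad)
validateAgainstReference(est$annual, sys$npp)$r2
#> [1] 0.5871897

# stable vs changing forest
cm <- classifyForestDynamics(sys$landcover)
cm
#> ChangeMap 48 x 48
#>   stable forest: 1371 px; changing forest: 587 px; unlabeled: 346 px

# per-pixel trend + persistence on the estimated NPP
tt <- trendAnalysis(est$annual, mask = sfMask(cm) | cfMask(cm))
ht <- hurstAnalysis(est$annual, mask = sfMask(cm) | cfMask(cm))
head(areaProportions(tt, dims = dim(sfMask(cm))), 3)
#>   subregion                class count area proportion
#> 1       all significant decrease   264  264  0.1348315
#> 2       all significant increase   234  234  0.1195097
#> 3       all      slight decrease   730  730  0.3728294

# driver attribution with exact SHAP
tab <- buildDriverTable(sys$npp,
                        list(pre = sys$pre, tem = sys$tem, srad = sys$srad),
                        list(elevation = sys$elevation, slope = sys$slope,
                             aspect = sys$aspect),
                        list(ha = sys$ha, age = sys$age, ftype = sys$ftype),
                        mask = sfMask(cm) | cfMask(cm), seed = 11)
model <- fitRf(tab, budget = 0, seed = 11)
shap <- shapEffects(model, evalCap = 200, seed = 11)
head(rankDrivers(shap), 3)
#>   feature importance rank  tied
#> 1     Pre  0.4718655    1 FALSE
#> 2     Ele  0.2146275    2 FALSE
#> 3     Tem  0.1941042    3 FALSE
```

The numbers mean: the CASA estimate tracks the synthetic truth (OLS R² ≈
0.59 over pooled pixel-years at these noise levels — the estimate and the
truth deliberately share only the NDVI pathway); about 70% of forest
pixels are stable forest; and precipitation is correctly recovered as the
dominant driver of the synthetic response surface, with elevation and
temperature next.

A full pipeline run (`runPipeline(list(out_dir = "out", seed = 1))`, or
the `inst/scripts/npplab.R` command line) writes every intermediate
product — rasters as `.asc`, tables as CSV, model metadata as JSON — plus
a log with the seed and per-stage counts. The config schema is the
`configDefaults` list documented in `?readRunConfig`: study period
(`first_year`/`last_year`), grid size, `alpha`, `change_fraction`,
`sample_cap`, `tuner_budget`, `eval_cap`, optional `casa_params` CSV and
`subregions` raster, `out_dir`, `seed`.

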