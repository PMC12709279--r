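# cwuetrend

Pixel-wise analysis of carbon and water use efficiency (CWUE) raster time
series: nonlinear trend extraction, trend-pattern classification,
persistence/stability grading, and machine-learning driver attribution.

## The problem

Ecosystem carbon and water budgets are coupled through three efficiency
ratios computed from annual flux rasters:

* **CUE = NPP / GPP** — carbon use efficiency, the fraction of gross
  primary productivity retained as net productivity (unitless);
* **WUE_GPP = GPP / ET** and **WUE_NPP = NPP / ET** — water use
  efficiency, carbon gained per millimetre of evapotranspired water
  (g C m⁻² mm⁻¹).

Given two to four decades of annual rasters, researchers ask: where is
CWUE rising or falling, and is the change monotone or hump-shaped? Will
the change persist? How stable is it year to year? And which
environmental or socioeconomic driver dominates it at each location?
`cwuetrend` implements that full chain for gridded annual data, and ships
a synthetic-scene generator with planted ground truth so every stage is
testable end to end without external downloads.

## Methods at the core

* **EEMD trend extraction.** Ensemble empirical mode decomposition with a
  from-scratch sifting core (Rcpp): cubic-spline envelope-mean sifting
  under the Cauchy-type SD criterion
  `Σ (h_k − h_{k−1})² / h_{k−1}² < 0.2` plus the defining IMF property,
  white-noise ensembles averaged componentwise. The secular trend is the
  residual `R(t)` in `x(t) = Σ IMF_i(t) + R(t)`; reconstruction is exact
  to 1e−10 relative.
* **Five-class trend patterns.** Monotone increasing/decreasing, increase
  then decrease, decrease then increase, or not significant. Significance
  combines a Mann–Kendall test on the raw series with an amplitude floor
  calibrated on the white-noise null of the trend estimator; hump calls
  require the dominant interior extremum to deviate from the endpoint
  chord by at least half the trend range.
* **Persistence & stability.** Hurst exponent by rescaled-range (R/S)
  analysis (`H > 0.5` persistent, `< 0.5` anti-persistent, `= 0.5`
  random); coefficient of variation with tiers HIGH (≥ 0.3), MEDIUM
  (0.1–0.3), LOW (≤ 0.1); both combined with the trend pattern into
  sustainability labels and roman-numeral stability grades.
* **Driver attribution.** A gradient-boosted regression (xgboost) of the
  CWUE indicator on six drivers — temperature, precipitation, sunlight,
  radiation, LAI, GDP — tuned by seeded random search with k-fold
  cross-validation, then explained by *exact interventional Shapley
  values* (full 2⁶ coalition enumeration against a background sample; the
  contributions satisfy `ŷ = y_base + Σ_j φ_j` to machine precision).
  Per-pixel mean |φ| yields dominant-driver maps and area fractions.

See `vignettes/cwue-trend-methods.Rmd` for the complete methods account,
parameter defaults and limitations.

## Worked example

```r
library(cwuetrend)

# a 12 x 12 x 19-year synthetic scene with planted trend archetypes
scn <- generate_scene(scene_config(height = 12, width = 12, seed = 42))
wue <- compute_wue(scn$npp, scn$et)
wue
#> <raster_cube> 19 years (2000-2018), 12 x 12 grid, 137/144 valid cells

# per-pixel EEMD trend classification
pm <- classify_cube(scn$gpp, eemd_config(seed = 42))
pm$area_fraction
#> # A tibble: 5 × 3
#>   pattern         n_pixels fraction
#>   <chr>              <int>    <dbl>
#> 1 MONO_INC              34    0.248
#> 2 MONO_DEC              34    0.248
#> 3 INC_DEC               35    0.255
#> 4 DEC_INC               34    0.248
#> 5 NOT_SIGNIFICANT        0    0
```

The scene plants the four archetypes in quadrants (~25% each after
masking); every unmasked pixel is recovered, so the area fractions echo
the planted shares and sum to 1. Per-pixel persistence and stability:

```r
px <- cube_pixel(scn$gpp, 2, 2)
hurst_rs(px, min_window = 4)$H            # 1.0  (strong trend dominates R/S)
coefficient_of_variation(px)              # 0.067
stability_grade(0.067, "MONO_INC")$grade  # "XLII" (low fluctuation, mono. inc.)
sustainability_class(1.0, "MONO_INC")
#> "Sustainability and monotonically increasing"
```

A 19-point Hurst estimate saturates when a strong trend dominates the
centred cumulative sums — per-pixel H maps on short records are
qualitative (see the vignette's limitations section).

Driver attribution on the same scene (LAI planted dominant on the west
half, temperature on the east):

```r
tab <- build_sample_table(wue, scn$drivers)
fit <- tune_and_fit(tab, booster_search_space(n_iter = 8, k_folds = 5, seed = 1))
shap <- shapley_values(fit$model, tab, background = 40, seed = 1)
dom  <- dominant_driver_map(shap, grid_dim = attr(tab, "grid_dim"))
dom$dominant_fraction   # ~0.5 lai / ~0.5 temperature
autoplot(shap)          # importance bars; autoplot(pm) maps the patterns
```

A command-line front end over the same functions lives at
`inst/cli/cwue-trendlab.R`
(`Rscript cwue-trendlab.R run-all --config run.json --seed 1`), and
`run_pipeline()` executes the whole chain with a checksummed output
manifest.

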