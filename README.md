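# seasonalLUR

Seasonal land use regression (LUR) modelling of NO₂ exposure surfaces.

Urban NO₂ is monitored at a sparse set of sites, yet exposure assessment
needs concentrations everywhere. LUR bridges the gap by regressing
monitored concentrations on the land characteristics surrounding each site
— road length, land-use class areas, population density and climate, each
aggregated over a disc ("buffer") of an optimized radius — and applying
the fitted model across a 30 m grid. `seasonalLUR` implements the full
seasonal pipeline for analysts and exposure modellers:

* **Buffer extraction** of covariates at radii 100–1000 m (100 m steps),
  with a single cell-center disc-membership rule shared by site-level
  extraction and focal (moving-window) grid statistics, and exact
  segment–circle clipping for vector road length.
* **Buffer optimization and two-stage screening**: the radius maximizing
  Pearson |r| against seasonal concentrations per variable; a response
  screen (|r| ≥ 0.2) and a collinearity screen (pairwise |r| ≤ 0.7,
  weaker-versus-response member dropped).
* **Bidirectional stepwise OLS** per season (entry p ≤ 0.05, removal
  p > 0.10, full-refit p-values) with pooled 10-fold cross-validation
  RMSE and adjusted R².

  C_s = β₀s + Σⱼ βⱼs·xⱼs(rⱼ) + ε,  reported in ppb (coefficients in ppm/unit)

* **Spatialization** on the 30 m grid, classification into low/medium/high
  bands at 30 and 40 ppb, annual aggregation, and **climate-scenario
  re-prediction** (temperature offsets, precipitation scalings) with land
  use held fixed.
* A **synthetic metropolitan-region generator** whose seasonal
  concentrations come from built-in ground-truth models, so every stage is
  testable by parameter recovery (see the methods vignette,
  `vignettes/seasonal-lur-methods.Rmd`).

## A worked example

```r
library(seasonalLUR)
bundle <- runPipeline(pipelineConfig(nSites = 125, seed = 1))
print(pipelineReport(bundle))
```

The run simulates a 12 × 12 km region with 125 monitoring sites, builds the
covariate cube, screens variables, fits the four seasonal models, maps them
and re-predicts under two bundled warming scenarios. The report prints a
tabular coefficient summary (ppm per covariate unit); with seed 1:

```
             term    spring   summer     fall   winter
         constant  2.15e-02 1.34e-02 2.78e-02 2.75e-02
      road_length  5.57e-05 5.97e-05 4.03e-05 4.17e-05
 residential_area  2.85e-07 1.91e-07 1.64e-07 2.85e-07
      temperature  0.00e+00 3.47e-05 3.25e-05 3.40e-05
 ...
 adjusted_R2  0.668  0.752 0.561  0.601
 cv_RMSE_ppb  4.646  3.461 5.189  4.955
```

The generating models behind this fixture have constants
0.023/0.015/0.025/0.031 ppm and, e.g., road-length coefficients
5.9/5.5/3.7/4.3 × 10⁻⁵ — at 125 sites the fit tracks them within its
standard errors, and zero entries mark terms the stepwise excluded. The
level-fraction table shows the seasonal gradient (winter most polluted,
summer cleanest) and the modest shift of area from the low into the medium
and high bands under the warming scenarios.

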