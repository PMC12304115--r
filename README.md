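# fishscape

Rivers integrate their landscapes: what grows, is farmed, or is built on
the land upstream shapes which fish live in the channel below. `fishscape`
implements a spatially explicit model that attributes riverine fish species
richness (and individual species' occurrence) to terrestrial land use and
land cover (LULC), by integrating each land-cover class's influence over
the flow-routed catchment of every survey site with an exponential
distance-decay kernel. It is written for freshwater ecologists and
biodiversity modelers who have a D8 flow-direction raster, a categorical
land-cover raster, and site-level richness or presence/absence (e.g. from
eDNA surveys), and who want to estimate *how far* and *how strongly* land
cover reaches into the river — and to project richness under land-cover
change.

## The model

Observed richness $B_i$ at site $i$ is modeled as

$$B_i \;=\; a + b\,\ln Q_i \;+\; \sum_{k=1}^{K} V_k\,
\frac{3}{r}\sum_{j:\,\mathrm{class}_j=k} A_j\,e^{-3 d_{ij}/r}
\;+\; \varepsilon_i,\qquad \varepsilon_i\sim\mathcal N(0,\sigma^2)$$

with $Q_i$ river discharge, $A_j$ pixel area, $d_{ij}$ the flow distance
from pixel $j$ to site $i$, $V_k$ the effect magnitude of class $k$, and
$r$ the **effective distance**: the kernel $f(d)=(3/r)e^{-3d/r}$ falls to
$e^{-3}\approx 5\%$ of its at-site value at $d=r$. The linear parameters
have a closed-form solution at fixed $r$; $r$ itself is estimated by
profile maximum likelihood (grid plus golden-section-style refinement).
Inference comes as likelihood-ratio tests, 50%/90% profile confidence
intervals, leave-one-out cross-validation, site-resampling bootstrap, and
collinearity/residual diagnostics. A logistic variant fits single species,
assigns each to its highest-effect class, and binarizes predicted maps at
the TSS-optimal threshold. Projection tools produce per-pixel terrestrial
effect maps, channel richness maps, and percent-change maps between
land-cover epochs, and a simplified neutral metacommunity model serves as
a land-cover-free null.

Because the study rasters this kind of analysis runs on are large and
proprietary to their providers, the package ships a first-class synthetic
landscape generator (dendritic D8 network, gradient-structured land-cover
mosaic, area-proportional discharge, channel-placed survey sites) so every
stage is testable end to end; rasters are exchanged as plain-text ESRI
ASCII grids.

## Worked example

```r
library(fishscape)

theta <- list(r = 19, a = 20.585, b = 3.550,
              V = c(1.438, -0.238, -2.163, -4.857, -3.684))
land <- generate_landscape(seed = 7)               # 120x120, 40 sites
gen  <- generate_observations(land, theta, sigma = 5, seed = 1007)
dat  <- richness_data(gen$obs, land$fields, land$lulc, land$areas)
fit  <- fit_richness(dat, r_bounds = c(1, 80))
print(fit)
ci <- profile_ci(dat, fit, "r", 0.90)
cat(sprintf("90%% profile CI for r: %.1f - %.1f km\n", ci$lower, ci$upper))
cv <- loocv_richness(dat, r_bounds = c(1, 80), n_grid = 30)
cat(sprintf("LOOCV RMSE: %.2f species\n", cv$rmse))
```

prints

```
Richness model fit (40 sites)
  r = 30.645 km, a = 22.621, b = 4.113
  V = 0.969, -0.925, -2.447, -4.973, -30.626
  sigma = 4.478, -2l = 233.446, adj R2 = 0.427
90% profile CI for r: 10.4 - 80.0 km
LOOCV RMSE: 5.46 species
```

Reading this: the data were simulated with an effective distance of 19 km
and class effects (1.4, −0.2, −2.2, −4.9, −3.7); the fit recovers the sign
pattern (class 1 positive, classes 3–5 negative; class 5 covers only ~1%
of the map, so its magnitude is poorly pinned), explains ~43% of richness
variance after penalization, and the 90% profile interval for $r$ —
10–80 km around a point estimate of 31 km — honestly reflects how much a
40-site survey on a 36-km landscape can say about the spatial range. The
methods vignette (`vignettes/fishscape-methods.Rmd`) quantifies this
identifiability ceiling.

## The analysis workflow

The numbered scripts under `analysis/` run the full study pipeline on the
synthetic system and write their tables under `results/`:

| stage | what it does |
|---|---|
| `01_simulate.R`  | landscape + site observations at the reference parameter values |
| `02_fit_richness.R` | profile-ML fit, LRTs, profile CIs, VIFs, variance components, upland/lowland split |
| `03_validate.R`  | leave-one-out CV and 200-draw bootstrap |
| `04_project.R`   | terrestrial effect map, channel richness map, bootstrap IQR layer |
| `05_species.R`   | per-species logistic fits, associations, TSS thresholds, presence maps |
| `06_scenarios.R` | merged-cropland refit, future land-cover conversion, percent-change map, assemblage Jaccard |
| `07_nmc_null.R`  | calibrated neutral metacommunity null vs the land-cover model |

Each is a thin driver over the package functions; run them in order with
`Rscript analysis/01_simulate.R` etc.

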