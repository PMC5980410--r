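# canopychange

Individual-tree growth, loss, and aboveground-biomass change from two
airborne lidar acquisitions over the same forest.

Repeat-pass lidar can, in principle, measure the fate of every tree on a
landscape: how much each surviving crown grew in height between surveys,
and which crowns fell or were harvested. In practice the two acquisitions
differ — instrument, return density, footprint, flight lines, scan angles,
geolocation — and those differences contaminate naive crown-to-crown
comparisons. `canopychange` implements a complete, testable chain for this
problem, aimed at tall, open-canopy conifer forest:

* DEM, smoothed canopy height model (CHM) and iterative **multistory
  watershed crown delineation** per epoch;
* scan-angle filtering (±15°), return-density homogenisation and
  GCP-based affine co-registration to make the epochs comparable;
* **growth**: centroid-overlay crown matching under four quality filters
  (reciprocal containment, <5 m height change, <1 m DEM difference,
  <100% radius change), summarised by height class;
* **loss**: watershed segmentation of the CHM difference, matched to
  first-epoch crowns (<3 m height and <30% area disagreement);
* **biomass**: a height-to-diameter model `DBH = a·ht` (site default
  `a = 2.2` cm/m, residual RMSE 15.5 cm) feeding the Jenkins true
  fir/hemlock equation

  ```
  biomass [kg] = exp(−2.5384 + 2.4814 · ln(DBH [cm]))
  ```

  with a per-tree error budget
  `σ_DBH/DBH = √((σ_ht/ht)² + (σ_a/a)² + (RMSE/DBH)²)`,
  `σ_m_dbh = M · 2.4814 · σ_DBH/DBH`, lognormal allometric scatter
  `σ_allom = M · e^{s²/2}√(e^{s²}−1)` at `s = 0.182329`,
  `σ_AGB = √(σ_m_dbh² + σ_allom²)`, linearly summed totals, and a
  quadrature change error — all validated against a Monte-Carlo oracle.

A synthetic-forest simulator (`generateScene`, `applyChange`,
`simulateAcquisition`, `simulateStudy`) produces paired acquisitions with
known per-tree growth and removals — including the 18 vs 13 returns/m²
and 15 vs 10 cm footprint asymmetry typical of mixed-instrument studies —
so the whole pipeline is verifiable against ground truth.

## Worked example

Simulate a 300-tree study with size-declining growth (0.8 m over 5 years
at 10 m of height, 0 at 60 m) and size-declining removal probability
(0.20 down to 0.05), then run the full pipeline:

```r
library(canopychange)

scen <- changeScenario(
  growthRateFn  = function(h) 0.8 * pmin(1, pmax(0, (60 - h) / 50)),
  growthSd      = 0.3,
  removalProbFn = function(h) 0.20 - 0.15 * pmin(1, pmax(0, (h - 10) / 50)))

st  <- simulateStudy(300, extent = c(180, 180), scenario = scen, seed = 7)
res <- runPipeline(pipelineConfig(heightFloor = 30),
                   cloud1 = st$cloud1, cloud2 = st$cloud2, gcps = st$gcps)
makeReport(res)
```

```
== Crown delineation ==
crowns epoch 1: 300   epoch 2: 249
count difference: 51 (17.0% of epoch 1)
mean crown height: 21.58 m -> 22.47 m
...
== Growth (matched crowns) ==
matches: 249, retained after filters: 248
mean height growth of retained matches: 0.62 m
height-growth medians by class (Spearman rho -1.00, p 0.083):
  10-15 m  n=43    median +0.85 m  [p10 +0.30, p90 +1.29]
  15-20 m  n=79    median +0.61 m  [p10 +0.29, p90 +1.09]
  20-25 m  n=35    median +0.59 m  [p10 +0.26, p90 +1.02]
  25-30 m  n=40    median +0.58 m  [p10 +0.19, p90 +0.92]

== Tree loss ==
detected loss events: 50 (watershed) vs count difference 51
overall loss rate: 16.7% over the interval (3.33%/yr linear, 3.58%/yr compound)
...
== Biomass ==
total biomass: 4.586e+05 +/- 3.174e+05 kg (69%) -> 4.1e+05 +/- 2.788e+05 kg (68%)
biomass change: -4.864e+04 +/- 4.719e+04 kg (97%)
mean per-tree fractional errors: height 2.1%, parameter 6.3%, residual 38.5%, DBH 39.2%
allometric fit CV: 18.4%
```

Reading it: all 300 planted trees were delineated in epoch 1; 51 of the
epoch-1 crowns have no epoch-2 counterpart, and the watershed loss
detector independently finds 50 loss events — the two loss estimates
agree to one tree. Matched survivors show the planted size-declining
growth gradient (medians falling from 0.85 m to 0.58 m across height
classes). The biomass block decomposes each tree's error into its height,
model-parameter and residual components; the residual DBH spread
dominates, and the 18.4% allometric CV is the lognormal
coefficient of variation implied by the biomass equation's log-space
standard error.

See the methods vignette (`vignettes/methods.Rmd`) for the models,
parameter meanings and defaults, and the design decisions behind each
stage.

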