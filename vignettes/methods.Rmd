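---
title: "Individual-tree change detection from multitemporal lidar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-tree change detection from multitemporal lidar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopychange)
```

## The problem

Tree growth and mortality drive the aboveground carbon flux of forests, but
both are classically measured in small field plots. Two airborne lidar
surveys of the same forest a few years apart contain, in principle, the same
information for every tree on the landscape: how much each surviving crown
gained in height, and which crowns disappeared. Extracting it is hard
because the two acquisitions are never alike — different instruments,
return densities, footprints, flight lines and scan-angle distributions all
perturb the apparent size and position of a delineated crown.

`canopychange` implements the full chain for a pair of acquisitions over a
tall, open-canopy conifer forest:

1. **Surfaces** — ground classification, DEM interpolation, and a smoothed
   canopy height model (CHM) per epoch.
2. **Crowns** — marker-controlled watershed delineation of the CHM,
   iterated into overstory and understory layers by vertically stratifying
   the returns inside each segment.
3. **Comparability** — a ±15° scan-angle filter, density homogenisation,
   and an affine co-registration fitted to ground control points.
4. **Growth** — centroid-overlay crown matching with four quality filters,
   then height-change distributions by size class.
5. **Loss** — watershed segmentation of the CHM difference, matched back to
   first-epoch crowns.
6. **Biomass** — a height-to-diameter allometry feeding the Jenkins
   true fir/hemlock biomass equation, with a fully analytic error budget
   validated against Monte-Carlo simulation.

A synthetic-forest simulator generates paired acquisitions with known
per-tree growth and removals, so every stage is testable against ground
truth — something no real acquisition pair offers.

## Surface models

Ground returns are classified by a two-pass minimum filter: the minimum
elevation per 5 m cell defines a provisional surface (bilinearly
interpolated between cell centres), and returns within 0.3 m of it are
ground. The DEM interpolates ground returns by tiled local least-squares
planes (10 m tiles, each fitted on the tile grown by half a tile); this is
exact on planar terrain and recovers the simulator's smooth sinusoidal
terrain to well under 0.25 m RMSE, comfortably below the 1 m DEM-difference
filter used later. Cells outside the convex hull of the ground returns are
nodata, and nodata propagates through every subsequent operation — it is
never silently treated as 0.

The CHM takes the maximum return elevation above the DEM per 0.5 m cell.
Two stabilising choices matter here:

* **Point splatting** (`splatRadius`, default 0.25 m). A per-cell maximum
  over a finite sample underestimates the true surface by an amount that
  shrinks with return density; two epochs at 18 and 13 returns/m² therefore
  disagree systematically even over unchanged canopy. Treating each return
  as a small disk rather than a dimensionless point (every cell its
  footprint touches sees its elevation) saturates the per-cell maximum and
  removes most of that density sensitivity.
* **Gaussian smoothing** (`smoothingSigma`, default 0.5 m). Watershed
  markers need a smooth surface, but an averaging kernel erodes crown
  peaks in proportion to the kernel variance times the crown's curvature —
  a *size-dependent* bias, strongest for small crowns, that leaks into
  height-change estimates whenever crown shape changes between epochs.
  Simulations across crown sizes showed 0.5 m keeps that differential bias
  within sampling noise while leaving segmentation stability unchanged;
  0.75 m is a reasonable alternative for noisier data and is one
  configuration switch away.

Empty canopy cells are pit-filled with the median of their valid 3×3
neighbours (else 0) before smoothing; smoothing renormalises its kernel
over valid cells so nodata does not bleed into the map.

## Crown delineation

Markers are the local maxima of the smoothed CHM at or above the minimum
tree height (2 m — separating shrubs and ground noise from trees) within a
3×3 window. Each canopy cell is assigned to a marker by steepest ascent on
the 8-neighbourhood; ties and plateaus are resolved deterministically by
scan order, so a delineation is bit-for-bit reproducible. The same
segmentation engine (an Rcpp priority assignment with documented plateau
handling) serves both the per-epoch crown maps and the tree-loss
difference layer, and the test-suite cross-checks it against an
independent brute-force steepest-ascent oracle on enumerable surfaces.

Multistory structure is recovered by stratifying the returns inside each
segment: ground hits (below 1 m) are discarded, a 0.5 m histogram is built,
and the largest empty vertical gap whose top lies below 70% of the segment
maximum is sought. If the gap spans at least 2 m and at least 10% of the
returns sit below it, the segment is split at the gap midpoint; understory
returns of all splitting segments are rasterised into a secondary CHM and
segmented again, iterating until no segment splits (at most 4 layers). The
10% fraction guards large segments against spurious splits from stray low
returns; detecting a small understory tree fully occluded by a dominant
crown requires lowering it, because an occluded crown contributes only the
few returns that penetrate the upper canopy. Both the gap parameters and
the fraction are configuration switches.

Crown attributes are: area from the cell count, radius as the
circle-equivalent `sqrt(area/pi)` (stable under density differences,
unlike a maximum-distance radius), centroid as the mean of cell centres,
and height as the *maximum smoothed-CHM value* in the segment — the
smoothed maximum is less sensitive to return-density differences than the
single highest return.

## Making two epochs comparable

Both clouds are filtered to |scan angle| ≤ 15° (inclusive boundary), since
oblique views occlude one side of a crown. The denser cloud is then
randomly thinned to the sparser epoch's areal density
(`equalizeDensity = TRUE`); without this, the residual density sensitivity
of the maximum surface leaves a systematic ~5 cm height-change offset that
would masquerade as growth or decline.

Registration is a least-squares affine transform fitted to ground
control point pairs, applied to the second epoch's crown centroids and (by
nearest-neighbour resampling onto the reference grid) to its label, CHM
and DEM rasters. The synthetic study generator derives GCPs from the
apices of the tallest surviving trees with a small digitisation jitter,
mimicking the manual identification of dominant crowns.

Matching overlays each first-epoch crown centroid on the registered
second-epoch label raster. Four quality filters then remove mismatches,
all as *strict* inequalities (a case exactly at a threshold is excluded):

| filter | rule | default |
|---|---|---|
| containment | centroids mutually inside the other epoch's crown | reciprocal |
| height | absolute height change below threshold | 5 m |
| terrain | DEM difference under the centroid below threshold | 1 m |
| radius | fractional crown-radius change below threshold | 100% |

Reciprocal containment is the stricter, symmetric reading of
"centroid of one year inside the delineation of the other"; the one-way
variant is a switch. The DEM difference is evaluated at the first-epoch
centroid cell. `filterSensitivitySweep()` re-applies the filters over a
threshold grid to show that the growth curve's shape is stable even as the
retained sample size varies severalfold.

## Growth and loss by size class

Height (and radius) changes are summarised in half-open 5 m classes of
first-epoch height: median, 10th/90th percentiles (type-7 linear
interpolation), and a notch half-width `1.57 * IQR / sqrt(n)` — the
standard boxplot approximation to a 95% confidence interval on the median.
Classes with fewer than 20 members are suppressed. A Spearman correlation
between class midpoint and class median quantifies the expected monotone
decline of growth with size. When several class medians are checked
jointly against a known truth, the test suite scales the notch to a
Bonferroni-adjusted family-wise level — twelve simultaneous 95% intervals
would otherwise fail by chance in nearly half of all runs.

Tree loss segments the difference surface (first-epoch CHM minus
registered second-epoch CHM; positive where canopy vanished) with the same
watershed, using the 3 m matching tolerance as the candidate-cell
threshold. Each difference segment is paired with the first-epoch crown of
maximal pixel overlap (ties: smaller height delta, then lower id) and
becomes a loss event iff heights agree within 3 m and areas within 30% —
again strict, and with both areas counted over the same ≥3 m height
support, since comparing an area defined at the 2 m tree cut against one
defined at the 3 m loss cut would systematically reject short crowns. A
first-epoch crown can appear in at most one event. Loss rates per height
class are events over crowns; the overall rate is annualised both linearly
(`rate/years`) and compound (`1-(1-rate)^(1/years)`) because both
conventions appear in practice, and the package privileges neither.
`countBasedLoss()` provides the coarse site-level cross-check — the
difference in delineated crown counts — which on synthetic scenes agrees
with the event-based count to within a few percent.

## Biomass and its error budget

Stem diameter is predicted from height by a zero-intercept least-squares
fit `DBH = a·ht` (site default `a` = 2.2 cm/m, residual RMSE 15.5 cm,
21.6 %RMSE), and biomass per tree by the Jenkins generalized equation for
the true fir/hemlock group,

```
biomass [kg] = exp(-2.5384 + 2.4814 · ln(DBH [cm])),
```

whose residual spread in log space is 0.182329.

The error chain, per tree of height `ht` and predicted biomass `M`:

* **Height measurement error** `sigma_ht`: matched crowns above 50 m are
  assumed not to grow, so their apparent height changes measure the
  extraction error. The default estimator is the mean absolute difference;
  the SD of differences is a switch. The error is treated as constant in
  absolute terms across sizes, because apex detection does not improve for
  short trees.
* **Fractional DBH error**: the root sum of squares
  `frac_dbh = sqrt((sigma_ht/ht)^2 + (sigma_a/a)^2 + (rmse/DBH)^2)`. The
  residual term belongs in the combination: it dominates the budget for
  typical trees.
* **Amplification**: `sigma_m_dbh = M · 2.4814 · frac_dbh` — the exponent
  of the biomass equation multiplies fractional errors.
* **Allometric scatter**: a log-space residual `s` means multiplicative
  lognormal error, with SD `sigma_allom = M·exp(s²/2)·sqrt(exp(s²)-1)`
  (the square root of the lognormal variance `exp(2s²+2mu) - exp(s²+2mu)`
  at `mu = ln M`) and CV `sqrt(exp(s²)-1)` ≈ 18.4% at `s = 0.182329`.
* **Per tree**: `sigma_agb = sqrt(sigma_m_dbh² + sigma_allom²)`.
* **Totals**: per-tree errors are summed *linearly* by default — they share
  the same fitted model terms and are treated as fully correlated —
  with independent (root-sum-of-squares) aggregation as a switch.
* **Change**: `sigma_change = |change| · sqrt(f1² + f2²)` where `f` is each
  epoch's fractional total error; the linear sum `|change|·(f1+f2)` is a
  switch. Quadrature is the default because it is the standard combination
  for a difference of two uncertain totals.

`monteCarloErrorOracle()` draws every source directly — height error per
tree, one slope draw shared by all trees per iteration (parameter error is
common to the fit), residual DBH error per tree, and lognormal
multiplicative scatter — and compares empirical SDs with the analytic
chain. Sources that enter a stage *linearly* agree to well under 2% at
10^5 draws: height, parameter and residual errors at the DBH stage, and
the allometric scatter at the biomass stage. The full budget is compared
at the biomass stage with a 10% tolerance: first-order propagation of a
~24% DBH error through an exponent of 2.4814 is inherently a few percent
optimistic relative to the exact moments of a powered Gaussian, and that
approximation error is part of the analytic method, not of its
implementation.

## What the simulator emulates — and what it does not

`generateScene()` draws tree heights from a truncated lognormal
(configurable), derives crown radii from the monotone allometry
`radius = 0.15·height + N(0, 0.3 m)`, and places trees tallest-first under
a minimum-spacing rule (centre distance at least 1.1 times the summed
crown radii). The non-overlapping default reflects the open structure of a
mature, fire-suppressed mixed-conifer stand, and keeps dominant crowns
resolvable — the precondition of any CHM-based delineation study. Terrain
is a sum of 2–4 low-frequency sinusoids rescaled to a stated total relief:
smooth, band-limited, and exactly known.

Crowns are vertical half-ellipsoids from the crown base (default 0.5 of
tree height) to the apex, chosen so apex heights are analytically
checkable. `applyChange()` removes each tree independently with a
height-dependent probability and grows survivors by a height-dependent
mean plus Gaussian noise (radii grow along the 0.15 allometry so crown
shape stays self-consistent). `simulateAcquisition()` samples returns as a
homogeneous Poisson process, places them on the terrain or the highest
crown envelope within half a footprint of the return position, lets a
configurable fraction of crown pulses penetrate to an overtopped second
crown and then the ground, adds vertical noise (default 0.1 m, a typical
ranging accuracy), applies the epoch's horizontal offset, and assigns scan
angles from the distance to the nearest of several parallel flight lines
flown with side lap at 600 m.

Defaults for the two epochs mirror the acquisition pair the method is
designed around: 18 returns/m² with a 15 cm footprint versus 13 returns/m²
with a 10 cm footprint, both scanning to at most 25°, with a ~1 m
horizontal mis-registration between them.

The simulator does *not* model full waveforms, occlusion ray-tracing,
species-specific reflectance, within-crown gaps, standing dead trees, or
partial crown breakage. Passing tests on synthetic scenes therefore
demonstrate that the chain is correct and unbiased under the stated
geometric and sampling model; they cannot certify behaviour on real
acquisitions, where crown shapes are irregular and acquisition differences
are richer than density, footprint and offset.

## Numerical choices and degenerate inputs

* All randomness flows through explicit seeds; every stage is bit-for-bit
  reproducible, including watershed tie-breaks (scan order).
* Grids combine only when exactly aligned (same origin, resolution,
  shape); anything else is an error, never an implicit resample.
* An all-background CHM yields an empty labelling, not an error; a
  growth-only difference surface yields zero loss segments.
* Degenerate registration inputs (<3 GCPs, collinear GCPs) and degenerate
  DEM geometry are errors with explicit messages; a one-pair allometry fit
  returns the slope with `NA` uncertainty and a warning.
* Thresholds are strict inequalities throughout, and each boundary is
  exercised by a dedicated test.

## Problem sizes used by the test suite

Unit tests run on scenes of 1–200 trees at 30–170 m extents. The
end-to-end recovery test uses a 2,000-tree scene on 450 × 450 m (about
6.3 M returns across both epochs) with size-declining growth (0.8 m at
10 m of height to 0 at 60 m, SD 0.3 m) and size-declining 5-year removal
probability (0.20 down to 0.05); it completes in about a minute. The
Monte-Carlo oracle runs 10^5 draws per comparison. These sizes were chosen
so the full suite exercises every claim at meaningful sample sizes while
remaining quick enough to run on every change.

## Known limitations

* Heights come from the smoothed CHM maximum; the residual footprint
  difference between epochs leaves a ~2 cm height-change offset in
  simulations — negligible against the growth signal, but not zero.
* The loss detector finds *crown disappearance* (fall or harvest), not
  physiological death: a standing dead tree keeps its crown surface.
* Small understory trees occluded by dominants are only detectable when
  enough pulses penetrate; their growth and loss statistics are biased
  toward the visible canopy.
* The count-based and event-based loss totals agree only when the two
  epochs' delineations are comparably complete; gross density disparities
  should be homogenised (the default) or the comparison treated with
  caution.
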