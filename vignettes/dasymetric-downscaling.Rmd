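---
title: "Age-stratified dasymetric downscaling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stratified dasymetric downscaling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Census population counts come attached to administrative units of wildly
varying size, much of whose area nobody lives in. Dasymetric mapping
redistributes each source-zone count over a fine target lattice using
ancillary covariates that predict where people actually are. `dasypop`
implements this for age-stratified counts: one independent mapping per
population group (total, 0–14, 15–59, 60–64, 65+), so the age structure
itself can vary from cell to cell instead of being inherited wholesale
from the source unit.

The central contract is pycnophylactic (mass-preserving): for every source
zone $z$ and group $g$,
$$\sum_{c \in z} \widehat{pop}_g(c) = P_{z,g}$$
exactly. Downscaling refines *where* a count sits; it never invents or
loses people.

## The weighting model

Per group, zone-level population density $D_{z,g} = P_{z,g}/A_z$
(persons/ha; $A_z$ the zone's inhabited area) is regressed on eight
zone-mean covariates with a random forest. Density is deliberately left
untransformed: a log transform would shrink the errors of the densest
zones, which are exactly the places a fitness assessment should weight.

Assumptions worth stating:

* the covariate–density relationship learned *between zones* transfers to
  *within-zone* cells (the usual, untestable dasymetric leap — predictions
  are only ever used as relative weights within a zone, which blunts any
  calibration bias);
* all density signal passes through the eight covariates; residual
  spatial structure (cultural, historical, administrative) becomes
  irreducible error;
* the inhabited mask `(builtup > 0 OR height > 0) AND water == 0` is
  read with strict inequalities and no epsilon — any built presence
  qualifies a cell.

## Tuning protocol

* Candidate zones: those strictly inside the middle 99% of the group's
  density distribution (drop 0.5% per tail, linear-interpolation
  percentiles, strict exclusion). The filter needs at least 200 rows;
  below that it warns and passes everything through, since trimming tails
  of a tiny sample removes signal, not outliers. The filter is applied per
  group on that group's own density, consistent with per-group training.
* Split: one seeded 85/15 shuffle (train $\lfloor 0.85n \rfloor$). The
  same split seed is used for every group so all group models face the
  same geography.
* Grid search: every pair from 13 tree counts (5…1000) and 9 depth caps
  (10…100), scored by 5-fold CV RMSE with a fold assignment fixed across
  pairs; minimum RMSE wins, ties broken toward fewer trees then shallower
  depth (the cheaper, simpler model). The winner is refit on the full
  training set.
* `mtry` equals the number of covariates: with eight curated predictors
  there is nothing to decorrelate away, and full-feature splits are the
  common regression-forest convention for small predictor sets.
* Covariate aggregation to zones is the mean over inhabited cells,
  matching the inhabited-area denominator of the target; an all-cell mean
  is available as an option.

## Allocation

Within each zone, weights are the model's cell predictions (clamped at
zero as a guard; tree ensembles on nonnegative targets cannot go
negative), zeroed off the mask, normalized to the zone, and multiplied by
the count. Numerics:

* allocation runs per zone in double precision, and the residual
  $P_z - \sum_c \widehat{pop}(c)$ (a few ulps) is added to the
  largest-weight cell, so conservation holds to machine precision rather
  than merely to rounding;
* a zone with positive count but all-zero weights falls back to uniform
  allocation over its inhabited cells; a zone with *no* inhabited cells
  cannot receive its count — the count is reported as unallocatable and
  surfaced, never silently dropped or smeared elsewhere;
* zones missing a census row become nodata in every output grid; cell
  values are continuous persons/ha, never rounded to integers.

## The synthetic landscape

Real gridded ground truth does not exist, so the generator builds worlds
where it does:

* **zones**: a contiguous rectangular tessellation honoring
  province → city → county → township, default 4 × 5 × 10 = 200 townships
  on 400 × 400 cells of 100 m — large enough that the middle-99% filter,
  the 85/15 split and city-level summaries are all meaningful, small
  enough to run in minutes on one CPU;
* **covariates**: smoothed Gaussian random fields (FFT convolution,
  correlation length 12 cells) plus per-city urban-core kernels that raise
  built-up fraction, building height, nighttime light and POI density
  jointly — the correlated covariate structure real cities show. Slope is
  finite-differenced from the elevation field; water follows a
  low-elevation-biased field thresholded to the target areal fraction;
* **truth**: cell density is a nonlinear function of the covariates —
  increasing in built-up fraction and height, decaying with slope and
  road distance — plus additive Gaussian noise (default 1.5 persons/ha,
  about 17% of the noise-free cell-density SD, a low-noise regime in
  which the zone-level signal is recoverable), truncated at zero and
  zeroed off the mask;
* **age structure**: per-cell shares are a softmax over smooth log-share
  fields with three gradient components per group — easting, northing and
  urbanity. The urbanity components (e.g. working-age people concentrate
  in cities, the 65+ share rises in rural areas) are *learnable* from the
  covariates; the location components are not, and are kept small, since
  location-driven share variation is irreducible error for any
  covariate-based model. The reported total surface is defined as the
  exact cell-wise sum of the four group surfaces, and tabulated censuses
  rebuild `total` and `a60plus` from the group sums, so the census
  identities hold exactly rather than to float tolerance.

What the generator does **not** emulate: realistic geography (zones are
rectangles), covariate measurement error and registration slip, census
undercount, boundary-change mismatches, and the heavy right tail of real
megacity densities. Passing tests show the machinery is correct and the
protocol recovers known structure under fair conditions; they do not
certify accuracy on any real landscape.

## Validation battery

1. **Model goodness-of-fit**: held-out R² (1 − SS\_res/SS\_tot) and RMSE
   per group, plus impurity importances and partial-dependence curves
   (20-point sweep between each covariate's 1st–99th percentiles).
2. **Total vs summed ages**: the direct-total grid and the sum of the four
   independently mapped age grids are compared per city (Pearson r and
   cell RMSE over valid cells; mean and IQR across cities). Cities with
   fewer than 3 valid cells are skipped; constant grids yield an
   undefined r, reported as missing.
3. **Coarse-source validation**: the entire pipeline rerun from
   county-level counts, aggregated back to townships and compared with
   the township census. Agreement R² here is the squared correlation of
   the estimated-on-actual OLS fit, so proportional bias shows up in the
   slope (below 1 = underestimation of populous townships) rather than in
   R². Since fine-source mapping aggregated to its own source level is
   exact by conservation, the coarse-source figures bound fine-source
   accuracy from below.
4. **Spatial variation of proportions**: per-unit population SD
   (ddof = 0, configurable) of cell proportions at any admin level,
   against a baseline that multiplies county age shares into the total
   grid — the baseline's proportions are county-constant, so its
   within-township SD is identically zero, making the ordering a sharp
   qualitative check. City size classes for stratified reporting use the
   official five-class breaks, left-closed (a 1.0-million city is
   "large").

## Degenerate inputs and tie-breaks

Cell membership in rasterization is by cell-center containment; a center
claimed by two polygons through a shared boundary goes to the polygon
earliest in file order, while genuine same-level overlap (verified by
re-testing jittered points) is an error. Zonal aggregates of empty zones
are explicit missing values, never zero — downstream code must decide.
A proportion at a zero-population cell is nodata, not 0/0. Quantiles are
type-7 (linear interpolation) throughout; IQRs are 25th–75th percentiles.

## File formats

Grids are read and written as ESRI ASCII rasters (plain text, 17
significant digits, lossless for 64-bit floats) with a sidecar file
carrying the CRS identifier; censuses and reports are CSV/JSON.
Coordinates are treated as planar meters; the package deliberately does
no reprojection — co-registration is the caller's contract.

## Problem sizes

The shipped tests run the full protocol at 400 × 400 cells / 200
townships (about two minutes for the five-group 13 × 9 grid search) and
exercise unit-level behavior on 120 × 120 and 50 × 50 worlds, where
brute-force loop oracles verify every zonal computation to 1e-12.

## Known limitations

Single-process; no uncertainty quantification on the weights (a forest's
prediction variance is available in principle but unexposed); no temporal
projection between census years; no building-level allocation; synthetic
zones are rectangles, so boundary-geometry pathologies of real
administrative data are untested beyond the polygon rasterizer's own unit
tests.
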