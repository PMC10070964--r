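---
title: "Methods: grid harmonization, LST reconstruction and derived covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid harmonization, LST reconstruction and derived covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envgrid)
```

`envgrid` produces grid-aligned environmental covariates for
epidemiological modelling. This vignette documents the models and
procedures behind each stage, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
fixtures do and do not demonstrate about real data.

## Geographical levels and the master lattice

Processing happens at three levels: a local window in UTM zone 32N
(EPSG:32632) at 200 m, a country level on the same metric CRS at 1 km, and
a continental level on WGS84 (EPSG:4326). All metric products use cell
sizes that are integer multiples or submultiples of 1000 m and are snapped
to one master kilometer lattice, so layers of different provenance are
cell-by-cell comparable.

The master lattice needs an anchor. We fix it at the round-kilometer
top-left corner of each level's extent (for the local level,
`x = 600000, y = 5230000`). Any such round-kilometer anchor satisfies the
multiples/submultiples rule; what matters is that it is declared once and
shared, because the alignment guarantees (origins differing by whole
coarse cells, idempotent re-alignment) are relative to it.

Conventions used throughout: the grid origin is the *top-left corner* of
the top-left cell, row indices grow southward, extents are half-open
`[min, max)`, and sampling is cell-center registered. Nodata is carried as
`NA` inside the value matrix and serialized as a declared sentinel
(default −9999) in the plain-text ESRI ASCII grid files the package reads
and writes; CRS codes travel in a `.prj` sidecar. The UTM32N–WGS84 point
transform is the standard transverse-Mercator series on the WGS84
ellipsoid, accurate to centimeters inside the zone — three orders of
magnitude below the finest cell size used.

Resampling offers `nearest`, `bilinear` and `block-mean`. Block-mean (the
right operator when coarsening, e.g. 10 m reflectance to the 200 m
product) averages the valid input cells whose centers fall in each output
cell; a block with no valid input is nodata. Bilinear sampling drops the
weights of nodata neighbours and renormalizes the rest, so isolated gaps
do not bleed into their neighbourhood; all three methods therefore map a
constant field to the same constant.

`snap_resolution` rounds a native resolution to the nearest whole
kilometer (half-up, degrees converted at 111.32 km/°), *except* where the
product registry pins an explicit target: the 0.25° station-blend
reanalysis maps to 27 km and the 0.1° satellite precipitation product to
10 km. These two constants cannot both be derived from a single
degree-to-kilometer conversion (0.25° ≈ 27.8 km would round to 28), so
they are registry facts, not computed values.

## Quality screening

Quality bytes are decoded into the mandatory-QA field (bits 0–1) and the
data-quality field (bits 2–3); the remaining bits (emissivity/LST error
classes) are exposed raw but not acted on by the default policy, because
their interpretation is product-specific. The default policy accepts
mandatory-QA codes {0, 1} (produced, good or usable quality) — common
practice for thermal products — and rejects scene-classification classes
{0, 1, 3, 8, 9, 10} (no-data, saturated, cloud shadow, medium/high cloud,
cirrus). Both sets are configurable. Scene eligibility uses a *strict*
comparison: a scene at exactly the 80 % cloud-cover ceiling is rejected.
Masking never alters a retained value and a stricter policy retains a
subset of a looser one; both properties are asserted in the test suite.

## The LST chain

Raw digital numbers convert as `T = 0.02·DN − 273.15` (the standard
thermal-product scaling, configurable), with 0 as fill. Cleaning then
applies two screens:

1. **Distribution screen.** Cells farther than `k_mad` (default 5) scaled
   median-absolute-deviations from the scene median are dropped. The MAD
   is floored at 10⁻⁶ so constant scenes pass unchanged. Five
   normal-consistent MADs is far in the tail — under Gaussian noise the
   false-rejection rate is below 0.1 % — so the screen only removes gross
   contamination (undetected cloud, sensor artifacts).

2. **Lapse screen.** Each scene (one date × overpass; fits are not pooled
   across scenes because the diurnal cycle shifts the intercept) gets an
   OLS regression of temperature on elevation. Cells with residuals beyond
   `k_sigma` (default 3) residual standard deviations are dropped. The
   fitted slope is the scene's apparent lapse rate, nominally near
   −0.0065 °C/m; a flat DEM makes the regression degenerate and is an
   error rather than a silent fallback.

**Reconstruction** fills every gap with the lapse-model prediction at the
cell's elevation *plus* a residual surface: a thin-plate spline through
the residuals at observed cells, exact at its anchors when smoothing is
zero. Observed cells always keep their values. When the observations are
coarser than the DEM (1 km observations, 200 m DEM) they are first
assigned to fine cells by nearest neighbour, so the output inherits the
DEM's resolution — the elevation term supplies the fine-scale structure.
Residuals are interpolated in 2-D (x, y); interpolating in 3-D
(x, y, elevation) is a possible extension, but the elevation signal is
already captured by the regression term, so 2-D residuals are smooth by
construction.

The dense spline solve is O(n³) in the anchor count, so anchors are
capped (default 400, taken as a regular spatial subsample of the valid
cells). On a noiseless linear-in-elevation scene the reconstruction is
exact regardless of the cap, because the residuals vanish; on noisy scenes
the cap trades a little residual-surface detail for bounded run time.

8-day composites are per-cell means of the valid observations in windows
starting at day-of-year 1, 9, …, 361 (windows restart each year; the last
window is short). Compositing accumulates in a canonical timestamp order,
so the result is exactly independent of input order.

## Spectral indices

NDVI and MNDWI are normalized differences, clipped to [−1, 1], with a
zero-denominator guard; EVI uses the standard coefficient set G = 2.5,
C1 = 6, C2 = 7.5, L = 1 and is left unclipped (its range is not bounded by
construction) but nodata-guarded where the denominator approaches zero.
Reflectances are assumed atmospherically corrected in [0, 1]; integer-
scaled inputs should be divided by their declared scale on read.

A 16-day index series is aligned to the 8-day thermal cadence by
*inserting* a per-cell nodata-aware mean between each consecutive pair,
timestamped at the 8-day midpoint. Insertion (rather than replacement)
preserves the original acquisitions, which is the behaviour implied by
computing averaged images *from* two consecutive images.

## Station meteorology

Each provider's table dialect is described declaratively — station and
date columns, date format, and per value column the target variable code
and affine unit conversion — so harmonization is table-driven and new
dialects need no code. Failures (unparseable dates, missing or non-numeric
cells) are rejected row-by-row with reasons, never silently dropped.

Quality cleaning applies, in order: collapse of exact duplicates (one
survivor; surplus copies reported), rejection of *conflicting* duplicates
(same key, different values — both sides rejected, since neither can be
trusted), plausibility ranges (temperature [−50, 50] °C, precipitation
[0, 1000] mm/day, humidity [0, 100] %), and the per-station-day ordering
rule TMN2 ≤ TMD2 ≤ TMX2 (a violating triple is rejected whole). The ranges
are declared defaults, not inferences; every input record lands in exactly
one of accepted/rejected, and cleaning is idempotent.

Daily precipitation is interpolated with a regularized thin-plate spline:
`f(p) = a₀ + a₁x + a₂y + Σᵢ wᵢ φ(|p − pᵢ|)`, `φ(r) = r² log r`, solved
from the standard augmented system. `smoothing` (default 0.1, field units)
is a ridge on the kernel diagonal — zero gives exact interpolation at
stations; `tension` (default 40) rescales distances before the kernel, so
larger values make the surface more local and membrane-like. The affine
term reproduces constant and planar fields exactly at any smoothing.
Negative interpolated values are floored at zero; a configurable minimum
of 5 reporting stations is required. Humidity records are stored and
queryable but not interpolated — a continuous humidity product is future
work.

## Derived covariates

- **GDD**: Σ max(0, (Tmax+Tmin)/2 − Tbase); missing days are skipped and
  counted. Additive over partitioned periods.
- **De Martonne aridity**: P/(T+10), monthly variant 12p/(t+10); undefined
  (nodata) at T ≤ −10 °C.
- **Rainy days**: inclusive comparison (`prec ≥ threshold`, default 1 mm);
  "exceeding a threshold" does not fix strictness, so the inclusive
  convention is declared and a strict switch provided.
- **Windowed variability**: sample SD (n−1) and *excess* (Fisher) kurtosis
  per cell; SD needs ≥ 2 observations, kurtosis ≥ 4 and nonzero variance.
- **Bioclim**: the 19 standard variables from 12 monthly tmin/tmax/prec.
  Quarters are any 3 consecutive calendar months *with wrap-around*
  (Nov–Jan counts); ties are broken by the earliest start month. BIO15
  uses the conventional `mean + 1` denominator safeguard so arid climates
  do not divide by zero; BIO3 is nodata when the annual range BIO7 is
  zero. The implementation is tested for exact equality against an
  independently coded brute-force that enumerates all 12 quarters.
- **Monthly aggregation** from daily layers: mean for temperature, sum for
  precipitation; cells observed on fewer than 80 % of the month's days
  are nodata.
- **Land-cover percentages**: per zone, the share of valid class cells in
  each class; shares sum to 100 within 10⁻⁹, and an empty zone is
  reported rather than omitted.

## The synthetic fixtures

The generator produces, under a single integer seed: a smooth DEM (sum of
Gaussian hills, scaled to [0, relief]); thermal days of four acquisitions
whose truth is `T₀ + overpass offset + lapse·elev + smooth anomaly`, with
Gaussian observation noise, and a configurable fraction of cells
cloud-contaminated (implanted −25 °C bias) and flagged in the QC band;
multispectral scenes with painted vegetation / bare / water patches whose
band signatures put NDVI, EVI and MNDWI in known ranges (band noise is
truncated at 2.5 σ so the declared index bands hold by construction);
and station networks whose records come from smooth truth fields and are
re-serialized into two provider dialects with different column names, date
formats and unit scalings.

Defaults are chosen to emulate the operating conditions of the real
pipeline: lapse rate −0.0065 °C/m (the standard environmental lapse),
1 °C observation noise, 30 % cloud fraction (a moderately cloudy day),
60 × 60-cell fixture grids at 200 m so the full chain runs in seconds.
Everything is deterministic given the seed and leaves the caller's RNG
state untouched.

What the fixtures do *not* emulate: spatially correlated (non-Gaussian)
sensor noise, cloud fields with realistic spatial structure, orbit and
view-angle geometry, atmospheric effects, mixed pixels at patch borders,
and station networks with elevation-biased placement. Passing tests
therefore demonstrate the *algorithmic* correctness of each stage
(masking, fitting, reconstruction, aggregation) and parameter recovery
under the stated noise model — not retrieval accuracy on real satellite
archives.

## Numerical choices and problem sizes

Grid comparisons use a 10⁻⁹ tolerance on origins and cell sizes; snapping
arithmetic adds a 10⁻⁹-cell epsilon so exact boundaries do not flip on
floating-point noise. The MAD floor is 10⁻⁶; the EVI denominator guard
10⁻⁶; duplicate spline points are collapsed to their mean before the
solve, and a near-singular spline system falls back to a tolerant QR
solve.

The test suite runs the full local thermal chain on 40–50-cell-square
scenes, lapse-recovery at n = 10 000 cells and 20 seeded replicates,
spline recovery at 100 stations on an 80 × 80 km grid, and the bioclim
oracle on dozens of randomized climates; the whole suite completes in
well under a minute on one CPU. The acceptance script uses the same
scales. Sizes are configurable upward — the algorithms are vectorized and
scale linearly in cell count except for the capped spline solve.

## Known limitations

- Only the two CRSs the levels use are supported; the transform is not a
  general projection engine.
- Raster I/O is plain-text ASCII grid (universally readable by GIS
  toolchains) rather than compressed binary formats; large archives would
  want a binary backend.
- The lapse model is linear in elevation; strong inversions (valley cold
  pools) violate it and will be partially absorbed, partially filtered by
  the residual screen.
- Residual interpolation is 2-D; 3-D (x, y, elevation) anchoring is noted
  as an extension.
- The catalog encodes level but not extent or CRS in filenames; within a
  level that is unambiguous by construction.
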