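---
title: "Synthetic hemispheric images for terrain and canopy light availability: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic hemispheric images for terrain and canopy light availability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemirad)
```

## The model

`hemirad` estimates potential light availability at ground points from three
raster inputs: a fine local digital terrain model (DTM, nominally 5 m), a
coarse regional DTM (50 m), and a canopy height model (CHM, 1 m), plus a
10 m evergreen/deciduous mix-rate raster for foliage density. The central
intermediate is a binary hemispheric image: for every direction on a regular
(zenith, azimuth) grid — 1° × 1° by default, bin centres at half-degrees —
the direction is either *sky* or *obstructed*. All downstream quantities are
functionals of this image.

### Terrain stage

The terrain skyline is computed in two stages and combined by per-azimuth
maximum. The local stage scans the fine DTM out to 300 m; the regional stage
scans the coarse DTM out to 25 km. Running the regional stage over its full
radius (rather than only beyond 300 m) and taking the maximum makes the
result insensitive to whether the stages overlap or partition. Each azimuth
ray is sampled at half-cell intervals with bilinear elevation interpolation:
half-cell sampling keeps aliasing below the grid's own resolution, and
bilinear interpolation is exact on locally planar terrain, so inclined-plane
fixtures agree with their closed form to rounding error. The horizon angle
per azimuth is `max atan((z − z_viewer)/d)`; negative values (terrain
everywhere below the viewer) are retained in the profile but floored at 0
when the image is built — a depressed skyline never opens the lower
hemisphere. The viewer sits at the ground surface (height 0) unless
configured otherwise. Where the local DTM has nodata at a point, the
regional profile is used alone.

Earth curvature and atmospheric refraction over the 25 km radius are not
corrected; at 25 km curvature lowers the apparent horizon by roughly 0.1°,
below the 1° angular resolution of the image.

### Canopy stage

Below the canopy, every direction's ray is marched in 3-D at 0.5 m steps
(half the CHM cell) accumulating the length spent inside canopy volume. The
canopy occupies the full column from the ground surface to ground + CHM
height: a height model carries no crown-base information, so this is the
simplest volume model consistent with the data. CHM and foliage-density
lookups are nearest-cell (each 1 m cell is a crown column); the ground
surface is bilinear. Rays stop at the configured cap (300 m, matching the
local-stage radius), on leaving all input grids, or on rising above the
scene's maximum surface height, whichever comes first.

The probability that a beam penetrates along direction *t* is the
exponential path-length law

$$p_t = \exp\!\left[-G \sum \lambda\, l_t\right]$$

with projection function `G = 0.5` for randomly oriented foliage and
`λ` (m⁻¹) the effective foliage area volume density, accumulated cell by
cell along the path so spatially varying foliage is supported. For uniform
`λ` the cellwise sum reduces to `λ · l`, which the tests assert as a
consistency check.

The probability field is binarised into sky/obstructed. The default is a
seeded per-direction Bernoulli draw: the realised image has the correct
expected transmission per direction and is bitwise reproducible from
(seed, point id); the per-point seed derives from the global seed and the
point's manifest index so tiling and evaluation order do not change
results. Leaf-on and leaf-off at the same point share the same uniform
draws, so the leaf-on sky set is a subset of the leaf-off sky set whenever
`λ_on ≥ λ_off` cellwise — the layer-nesting property holds per direction
and per hour, not only in expectation. A deterministic threshold mode
(sky iff `p ≥ 0.5`) exists for regression work. The canopy image is
intersected with the terrain image: a direction must be free of both
terrain and canopy occlusion to be sky.

### Sky-view factors

Both SVF variants aggregate sky fractions of 10° zenith rings. Within a
ring, each cell is weighted by its solid angle (∝ sin of the zenith-bin
centre); this reproduces the pixel ratio of a rendered fisheye image
without committing to a projection (equiangular and equisolid renderings
differ only in how they allocate pixels across zenith, which the explicit
solid-angle weight replaces). Ring weights are analytic, not numerical:
`sin²θ₂ − sin²θ₁` for the planar variant (projected annulus area) and
`cosθ₁ − cosθ₂` for the hemispheric variant (spherical band area). Analytic
weights make ring-edge-aligned cases exact: a uniform 30° horizon gives
SVF-planar `sin²60° = 0.75` and SVF-hemi `1 − cos60° = 0.5` to machine
precision, which the test suite asserts.

### Solar track and direct-beam transmissivity

Solar zenith and azimuth come from the NOAA solar-calculator equation set
(Julian century → mean longitude/anomaly, equation of time, declination,
hour angle). The implementation is vectorised over UT Julian day; an
independently written scalar implementation working from calendar
components serves as the test oracle, and the two agree to well below
0.01°. Refraction is off by default — the model computes potential
geometry, and near-horizon directions are dominated by terrain — but the
NOAA correction is available behind a flag.

The track covers the calendar year (2020 by default: a leap year, 8784
hourly steps) at 2-minute cadence in fixed-offset UTC+1; daylight-saving
shifts are deliberately absent. DBT at one position is the sky fraction of
the image over the 0.53° solar disc. Because the disc is smaller than one
1° image cell, nearest-cell lookup would make DBT binary; the disc is
instead supersampled on a fixed 11 × 11 offset grid (97 points inside the
disc), recovering partial occlusion where the disc straddles a horizon or
crown edge. Disc samples falling at zenith ≥ 90° lie outside the image and
are excluded from the average rather than counted as obstructed, so a flat
open scene yields DBT exactly 1 whenever the sun's centre is above the
astronomical horizon and 0 otherwise — a step function, with fractions
reserved for genuine partial occlusion. Hourly values are arithmetic means
of the 30 fine steps in `[H:00, H+1:00)`, timestamped at `H:00`.

### Foliage density maps

`λ` endpoints are configuration, not calibration: estimating them requires
segmented lidar crowns and species allometry, which are out of scope. The
shipped defaults (evergreen 0.6, deciduous leaf-on 0.5, deciduous leaf-off
0.15 m⁻¹, larch leaf-on equal to evergreen, larch leaf-off 0.15) are
plausible magnitudes for alpine spruce and lowland beech but are
*uncalibrated placeholders* and documented as such. The 10 m mix rate is
replicated to 1 m by nearest neighbour and `λ` interpolated linearly
between the evergreen and deciduous endpoints; the deciduous endpoint is
broadleaf in broadleaf ecoregions and larch in needleleaf ecoregions.

The larch override deserves a note. Alpine larch stands are systematically
mislabelled by the standard products: the ecoregion expects needleleaf, the
dominant-leaf-type product reports broadleaf, and the mix rate calls the
pixel evergreen-majority. Where all three hold *and* the pixel is above
1500 m a.s.l., the model assumes a pure larch forest (full `λ` override,
not merely a changed interpolation endpoint — an evergreen-majority mix
would otherwise keep the pixel effectively evergreen and defeat the
purpose of distinguishing needle-shedding larch in winter). The elevation
gate is folded in as a hard conjunct so that lowland product disagreements
are not mislabelled as larch.

## Synthetic scenes and what the tests show

The scene module generates analytic terrain (flat, inclined plane, crater
with a rim subtending an exact angle from the centre, seeded Gaussian
hills) and procedural forests (single cuboid crown, plantation lattice,
uniform slab, seeded gapped stand), sampled to grids at the model's native
resolutions. Because the surfaces are closed-form, a dense 0.1 m
ray-marching oracle needs no interpolation assumptions; the suite asserts
that raster-based horizon angles agree with the oracle within one cell's
angular subtense and canopy path lengths within one 3-D cell diagonal
(`√3` × cell size — the longest path a ray can spend in one cell).

These fixtures emulate the *geometry* of terrain and forest structure:
occlusion, path lengths, nesting, calendar and encoding conventions. They
do not emulate real crown shapes (cuboids, not ellipsoids), understory,
within-crown density variation, or the error structure of lidar-derived
height models — so passing tests demonstrate geometric and statistical
correctness of the machinery, not calibration against real forests.

## Numerical choices and degenerate inputs

- Percent encoding rounds half-up (`floor(100v + 0.5)`): deterministic
  across platforms; at 1 % quantisation the asymmetry of round-half-even is
  irrelevant. Nodata in 8-bit layers is 255, outside the valid 0–100 range.
- Output layers quantised to 8 bits perturb reconstructed radiation by at
  most 0.5 % of the incoming flux, asserted in the tests.
- Angular grids must divide evenly (azimuth step into 360°, zenith step
  into 90°, ring width into 90°, track step into 60 min); constructors
  reject anything else rather than rounding silently.
- Horizon rays with no valid sample (all nodata) report −90° (open);
  a point whose neighbourhood is entirely nodata in both DTMs is an error.
- Geographic-CRS rasters are rejected at read time: all geometry assumes
  metric projected coordinates. Inverse projection to latitude/longitude
  (for solar geometry) supports Swiss LV95 via the swisstopo approximate
  series and a `LOCAL:<lat>,<lon>` tangent plane for synthetic scenes.
- Craters and walls aligned to ring edges make closed-form tests exact;
  everything else is compared against oracles with stated tolerances
  rather than magic constants.

## Problem sizes

The shipped tests and the acceptance script run on desk-scale fixtures
chosen to exercise every code path while staying quick: local grids of at
most 64 × 64 cells, 10 × 10 forest masks (up to ~100 model points), single
days of the 2020 track for per-point DBT (full-year tracks are used where
the calendar itself is under test), and 20-seed ensembles for binarisation
calibration. A national-scale run is the same code over a larger manifest;
`run_tiles` is resumable (existing output files are kept) and
order-independent by construction.

## Known limitations

- No crown-base height: the canopy volume is a column from the ground up,
  so trunk space below live crowns attenuates as if it were foliage.
- `λ` defaults are uncalibrated; users fitting real imagery should supply
  calibrated per-type values via `model_config()`.
- No Earth-curvature or refraction correction in the terrain horizon.
- Green-up/senescence transitions are out of scope: the model produces
  leaf-on and leaf-off endpoints, and blending across the season is left
  to the user.
- Direct/diffuse partitioning of combined forcing is not provided;
  `surface_swr()` expects pre-split components.
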