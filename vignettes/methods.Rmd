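---
title: "Thermal CWSI mapping for vineyards: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal CWSI mapping for vineyards: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

UAV thermal surveys of woody crops produce two kinds of product: a 2D thermal
orthomosaic and a 3D point cloud with per-point temperature. Canopy
temperature tracks plant water status -- a water-stressed vine closes its
stomata, transpires less, and warms up -- so both products can be turned into
maps of the Crop Water Stress Index,

$$\mathrm{CWSI} = \frac{T_\mathrm{canopy} - T_\mathrm{wet}}{T_\mathrm{dry} - T_\mathrm{wet}},$$

where $T_\mathrm{wet}$ is the temperature of a fully transpiring canopy and
$T_\mathrm{dry}$ that of a non-transpiring one. `vinecwsi` implements the
*simplified* (histogram-based) variant: after isolating pure canopy
temperatures, $T_\mathrm{wet}$ is the mean of the coolest 0.5% of the
canopy-temperature histogram and $T_\mathrm{dry}$ the mean of the warmest
0.5% (`tail_fraction`, default 0.005). This anchors the index to each
dataset's own temperature distribution; no energy-balance or air-temperature
baseline is attempted, and references are computed per dataset (per flight,
per data model), after noise filtering and masking.

The index is an affine map of temperature. The package leans on this
deliberately: the mean, min, max, and standard deviation of CWSI must equal
the affine images of the corresponding temperature statistics
(`cwsi_from_stats()`), and both the test suite and the acceptance script
verify published flight summaries through exactly this identity.

## Canopy isolation

**2D branch.** A canopy height model is the cellwise difference
`CHM = DSM - DTM`. Cells whose height *strictly exceeds* `threshold_m`
(default 0.5 m) become canopy; the strict inequality is intentional -- a cell
at exactly the threshold is not canopy. The mask then blanks every non-canopy
cell of the thermal layer. No-data propagates: a no-data cell in either
elevation model is no-data in the CHM and is never counted in any statistic.

**3D branch.** Ground points are classified by progressive TIN
densification: the lowest point per `cell_size` cell (default 1 m) seeds a
Delaunay terrain model; a candidate joins the ground when its vertical
distance to the containing triangle is at most `max_distance` (0.15 m) and
the angle it subtends to each triangle vertex -- measured from the
horizontal as `atan(|dz| / horizontal distance)` -- is at most `max_angle`
(15 degrees); the terrain is retriangulated for `n_iterations` (3) rounds.
The source workflow names this mechanism but not its parameter values; the
defaults here suit 3 m row spacing and are all exposed on the CLI. Two
implementation details matter in practice: seed cells must be large enough
that every cell contains true ground (a cell containing only canopy would
poison the terrain model), and the TIN is augmented with four virtual corner
vertices placed on a least-squares plane through the current ground set so
that points near the footprint boundary are judged by the thresholds rather
than falling outside the triangulated hull.

Noise filtering is statistical outlier removal: a point is discarded when
its mean distance to its `k_neighbors` (8) nearest neighbours exceeds the
global mean by `sigma_multiplier` (2) standard deviations. The GUI tool used
in the original workflow implements a different (plane-fit) filter with
unpublished parameters; equivalence is not claimed, only the same role.
Manual cloud editing is replaced by a deterministic rule,
`remove_understory()`: points below 0.5 m height above the interpolated
terrain are dropped, mirroring the 2D threshold. Reproducibility requires
eliminating the manual step; this is a design choice, not a claim that the
rule equals hand editing. `trim_bottom()` (default 0.20 m above the lowest
canopy height) reproduces the adjustment used to align a denser
reference cloud whose canopy reaches lower than photogrammetric clouds, and
`segment_top()` (0.25 m cells, 0.20 m depth) keeps the part of the canopy a
nadir orthomosaic sees; "top of the cloud" has no published definition, so
the per-cell depth window is this package's own, parameterised choice.

## Per-plant extraction and volumes

A rectangle aligned to the row azimuth and bounding the ROI is split into
`n_along` x `n_across` equal cells; ids run along rows, then across. Cell
membership is half-open in the rotated frame, so a sample on a shared edge
belongs to exactly one cell and per-cell counts always sum to the total --
the partition property the regressions depend on. The published analysis
used 51 polygons for its block; since the underlying ROI dimensions are not
published, grid dimensions are user parameters defaulting to the planting
pattern (2.5 m x 3 m). No correction is attempted for vines that do not
coincide with their cell; none is described in the source workflow either.

Per-plant canopy volume is the volume of the 3D convex hull of the cell's
cleaned canopy points. The hull of a sample inscribed in a convex body
underestimates its volume and converges from below as density grows; the
acceptance suite checks both the bound and the convergence direction.
Degenerate cells (fewer than 4 points, coplanar) yield `NA` and are dropped
from regressions -- this is the missing-plant path.

## The synthetic vineyard

The study's field data are not deposited, so every stage is exercised on a
generated scene with known truth (`generate_scene()`), a pure function of
its `scene_config()` (seed included; randomness is drawn in a documented
order). What it emulates, with defaults and why:

* **Layout**: 4 rows x 6 plants, 2.5 m between plants and 3.0 m between
  rows at a NE--SW azimuth (45 degrees) -- the published planting pattern of
  the studied vineyard; plants are independently missing
  with probability 0.05 ("occasional missing plants within rows").
* **Canopy solids**: ellipsoids spanning 0.5--2.3 m above terrain (base
  0.5 m = fruiting-wire height, vertical extent 1.8 m, radii 1.1 m along x
  0.5 m across -- a VSP hedgerow profile). Each plant carries a lognormal
  size factor (`plant_scale_sd` 0.15) on radii and height, with the base
  fixed: vigor varies, the trellis does not. Canopies are hedged at half the
  plant/row spacing, as mechanical VSP hedging keeps vines in their slot;
  this also keeps every plant inside its grid cell, so per-cell hulls
  measure their own plant. Truth volumes stay closed-form (ellipsoid
  segment minus hedging caps), verified against Monte-Carlo rejection.
* **Points**: canopy points sample the ellipsoid *surface* area-uniformly at
  `point_density` 250 per m^2 of canopy surface -- sensors (SfM, LiDAR)
  observe the canopy envelope, not its interior, and the published point
  distances (5.6--6.6 cm) correspond to roughly this density. Ground points
  (50 per m^2) lie exactly on the terrain, an inclined plane (slopes 0.03
  and 0.015 by default) so ground classification is non-trivially exercised.
* **Temperatures** (degrees C): soil 45 +/- 1.5 -- hotter than canopy, since
  soil thermal emission is what contaminates unmasked maps; canopy top 32
  with a vertical gradient of +2 per metre of depth below the plant's top,
  reproducing by construction the observed pattern of lower CWSI at the top
  of the canopy; Gaussian sensor noise 0.5 on every sample. The published
  flights span 31--56 degrees C, which these values bracket. Nadir- and
  oblique-like scenes are emulated by independent temperature parameters,
  not by a diurnal physics model -- the two real flights were hours apart
  and differ by ~10 degrees in maximum temperature, which a generator
  parameter, not a model, represents here.
* **Rasters**: terrain and canopy-top surfaces evaluated analytically at
  cell centers (0.10 m cells): the DTM is exact terrain, the DSM the upper
  envelope, the thermal layer the temperature of the visible surface plus
  noise.

What the generator does *not* emulate: SfM reconstruction error and doming,
occlusion and view-dependent sampling gaps, shadows, wind motion, mixed
pixels at canopy edges, emissivity and atmospheric effects, within-canopy
temperature heterogeneity beyond the vertical gradient. A green test
therefore establishes that the *pipeline machinery* -- masking, Eq.-style
index algebra, classification, clipping, hulls, regressions -- behaves
correctly on data with the stated geometry and thermal structure; it does
not validate the index agronomically, and the published real-data regression
strengths (R^2 of 0.72/0.68/0.54 against the reference cloud) are
explicitly out of reach without the field data. Those are covered instead by
a property: injecting growing measurement noise into paired volumes must
monotonically degrade R^2.

## Numerical choices

* Reference tails: the tail count is `max(1, round(f * N))` with
  half-away-from-zero rounding (the discretisation is not published);
  averaging runs over the sorted raw values, not histogram bins, which
  would add an arbitrary bin width. A degenerate reference interval
  ($T_\mathrm{dry} \le T_\mathrm{wet}$, e.g. a constant input) is an error,
  not a NaN.
* CWSI is never clipped to [0, 1]; the fraction outside is reported
  (`cwsi_outlier_fraction()`), mirroring the source treating such values as
  retained outliers (below 1% of points there).
* Rasters follow a half-open, top-left-origin, north-up convention;
  point-in-cell lookups use the same rule, so cloud-raster joins are exact.
  All coordinates are planar metric; differing CRS labels are an error and
  reprojection is out of scope.
* Temperature units are metadata declared by the caller, never inferred
  from magnitude (310 could be Kelvin or a broken Celsius reading).
* The 3D convex hull is an incremental algorithm with a scale-relative
  tolerance (1e-10 of the bounding-box span); volumes come from signed
  tetrahedra against an interior point. Degenerate inputs (< 4 points,
  collinear, coplanar) raise errors carrying the point count.
* OLS regressions fit the intercept (forced-origin is not indicated in the
  source); p-values use the F statistic and are labeled informational.
  Zero predictor variance is an error; zero response variance returns
  R^2 = 0 with a warning.
* GeoTIFF support is a minimal uncompressed codec (float32/float64/uint8,
  strip layout, geo tags, GDAL nodata); float32 is the default on write, so
  arbitrary doubles round-trip exactly only via `dtype = "float64"`. LAS is
  version 1.2 point format 0 (coordinates + class codes 2/5/7; richer
  attributes must use text or PLY, and asking LAS to carry them is an
  error). These codecs exist because the target environment provides no
  geospatial I/O package; they intentionally reject compressed or tiled
  variants.

## Known limitations

Single-CRS, in-memory processing only; the ground classifier assumes the
lowest return in a seed cell is ground (dense low canopy over every cell of
an area would defeat it); the noise filter is distance-based and will not
separate structured artifacts; hull volumes overestimate concave canopies
with gaps (a known property of the estimator -- voxel or alpha-shape
volumes are out of scope); and the synthetic world's simplifications listed
above bound what the tests can claim.
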