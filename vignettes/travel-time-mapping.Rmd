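---
title: "Methods: least-cost travel-time mapping on friction surfaces"
author: "timeraster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: least-cost travel-time mapping on friction surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeraster)
```

## The model

`timeraster` maps *accessibility*: given a set of point locations (health
facilities, transit stations, charging points, ...), it produces a raster
whose every cell holds the minimum travel time, in minutes, from that cell
to the nearest of the locations.

Movement is modelled as traversal of a resistance **friction surface**: a
raster whose cell values give the cost of moving through the cell in
*minutes per metre* — the reciprocal of speed. The canonical inputs are the
2020 global walking-only and motorised friction surfaces at 30 arc-second
(1/120°) resolution, whose walking values range from 0.012 min/m (a 5 km/h
walk) upward, but any single-band friction raster in the same units works.

The raster is treated as a graph. Cells are nodes; each unmasked cell is
connected to its 8 neighbours (queen's move). The cost of traversing the
edge between neighbouring cells $a$ and $b$ is

$$w(a,b) = d(a,b)\cdot \frac{f_a + f_b}{2}$$

where $d(a,b)$ is the distance in metres between the two cell centers and
$f_a, f_b$ are the cells' frictions. Averaging the two frictions makes the
edge symmetric; taking the *arithmetic* mean of friction (the default,
`averaging = "mean_friction"`) treats the move as spending half the
distance in each cell. The alternative `"mean_conductance"`,

$$w(a,b) = \frac{d(a,b)}{\tfrac12\,(1/f_a + 1/f_b)},$$

averages the two *speeds* instead, which is what transition-matrix
(conductance-based) raster toolkits compute. The two coincide exactly when
$f_a = f_b$, and mean_conductance is never larger (harmonic ≤ arithmetic
mean). The choice is recorded in the output metadata so downstream users
can tell which convention produced a file.

The travel-time raster is then the multi-source shortest-path distance: all
source cells are seeded at 0 and a single Dijkstra pass (binary heap,
implemented in C++) yields, for every cell, the minimum over sources of the
least-cost path. No A*-style heuristic is applicable since the full surface
is the output. Unmasked cells in connected components containing no source
— offshore islands after land masking are the archetype — are genuinely
unreachable and get `+Inf`, which the GeoTIFF writer encodes as the nodata
sentinel (with the infinite count preserved in metadata, since TIFF
consumers disagree about IEEE infinities). Masked cells are nodata
throughout, never 0.

### Distances on the globe

On geographic (lon/lat) grids, $d(a,b)$ is the great-circle distance
between cell centers — haversine on a sphere of radius 6 371 008.8 m (the
IUGG mean radius). At ~1 km cells, sphere-vs-ellipsoid differences are a
few parts per thousand, far below the uncertainty of any friction surface,
and the sphere keeps results deterministic and platform-independent. Using
true center-to-center metres has two consequences worth noting:

* east–west steps shrink with $\cos(\mathrm{latitude})$, so a minute of
  walking covers more grid cells near the poles;
* diagonal steps get their true length — there is no separate
  $\sqrt2$ correction factor, it falls out of the geometry.

On projected (planar) grids, $d$ is Euclidean in map units, and the uniform
closed form is the octile distance
$f\cdot s\,(\sqrt2\min(|\Delta r|,|\Delta c|) + ||\Delta r|-|\Delta c||)$,
which the test suite checks exactly.

## Grid conventions

The global surfaces live on the 30 arc-second lattice anchored at
(−180°, −90°). An arbitrary requested extent is *snapped* by moving each of
its four bounds to the **nearest** lattice line (ties toward +infinity);
this is the registration that reproduces the published Singapore example,
where the requested box (103.6091, 104.0858, 1.1664, 1.4714) becomes
(103.608333, 104.083333, 1.166667, 1.475), a 37 × 57 grid:

```{r}
snap_extent(tt_extent(103.6091, 104.0858, 1.1664, 1.4714))
```

Nearest-line snapping is not the only conceivable registration (a server
could snap outward), so the anchor and resolution remain arguments. Rows
are numbered from the north (north-up raster convention) and indices are
1-based as is idiomatic in R. Point-to-cell lookup uses half-open cells —
a point on an interior grid line belongs to the cell east/south of it —
with the extent's far edges closed so no point inside the extent is
orphaned. Extents that would cross the antimeridian cannot be expressed
(xmin < xmax is enforced) and are rejected rather than wrapped.

## Preparing friction surfaces

`prepare_friction()` covers the two supported sources:

* **Named global surfaces** (`"walk2020"`, `"motor2020"`) are served by a
  pluggable *fetch adapter* — any `function(name, grid)` returning the
  surface on the snapped grid — with an optional on-disk GeoTIFF cache
  keyed by name and snapped extent. No adapter ships enabled, so requesting
  a named surface without configuring one fails with an explicit "offline"
  error rather than a surprise download; everything else in the package
  runs without a network.
* **User rasters** are cropped to the area of interest *on their own grid*:
  no resampling ever happens, so every output value equals an input value.
  Silently regridding a friction surface would change travel times; users
  who need a different grid must resample deliberately, outside this
  package. The crop tolerates coordinates that were printed and re-parsed
  (bounds are matched to the grid within 10⁻⁶ of a cell) rather than
  demanding bit-exact alignment.

Masking by a polygon (typically a land boundary) removes cells whose
**center** falls outside; there is no fractional-coverage rule, so a cell
is either fully traversable or fully absent, matching the all-or-nothing
behaviour of island cells that survive a land mask but are disconnected
from the mainland. Membership uses the even-odd rule over all rings, so
holes and multipart polygons behave conventionally. Masking is idempotent
and masks only accumulate. Friction values are validated strictly positive
and finite; values above 10 min/m (slower than 6 metres per hour) warn
about a probable unit mistake but are not converted.

## The synthetic-data generator

`synth_friction()` produces the surfaces the test-suite and examples run
on: `uniform` (closed forms), `gradient` (deterministic heterogeneity),
`random` (log-uniform friction in [base, 5·base], seeded), and
`corridor_with_barrier` (a fully masked column splitting the grid in two,
exercising the infinite-time contract). The default `base_value` of
0.012 min/m is the walking surface's 5 km/h floor; the log-uniform range up
to 5× spans the published Singapore crop's spread (0.012–0.062 min/m).
These fixtures emulate the *scale and structure* of real friction surfaces
but not their spatial autocorrelation, road networks, or coastline
geometry — so passing tests demonstrate the graph computation and the
grid/IO contracts, not calibration against any real landscape.

## Numerical choices and degenerate inputs

* Travel times are exact sums of IEEE doubles along shortest paths; the
  engine is compared against an independently written edge-list
  Bellman–Ford to a relative 10⁻⁹ on random instances (200 instances up to
  20 × 20 cells with random masks, frictions and sources in the acceptance
  suite — sizes chosen to keep the whole suite under a minute while
  covering every code path).
* Nearest-source labels break exact ties toward the lower source index;
  with symmetric costs this makes catchment allocation deterministic and
  order-independent. Duplicate points in one cell collapse to a single
  source carrying the lowest point index.
* A source on a masked cell is a hard error by default — silently dropping
  it would fabricate an unreachable-looking catchment — with
  `drop_bad_points = TRUE` as the explicit opt-in downgrade to a warning
  (the same switch covers out-of-extent points). If *all* sources are
  masked or outside, that is always an error.
* Degenerate snapped extents (zero rows or columns) are rejected naming the
  offending axis; 1 × n and n × 1 grids are legal and tested.
* GeoTIFF output is float32 for travel time (minutes need < 7 significant
  digits; the writer rounds through float32 so in-memory and on-disk values
  compare equal) and float64 for friction (preserving native precision).
  The nodata sentinel defaults to −9999.

## Limitations

* Whole rasters are held in memory; continental extents at 30 arc-seconds
  need out-of-core tiling this package does not attempt.
* No reprojection, rotated grids, or sub-cell interpolation; 16-connected
  (knight's-move) graphs are not offered.
* Travel time is isotropic and static: no one-way streets, slopes, tides
  or time-of-day effects beyond what the friction surface encodes.
* Within a ~1 km cell, true walking times vary; results inherit the
  friction surface's resolution.
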