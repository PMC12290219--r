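# timeraster

Travel-time rasters from friction surfaces and point locations.

Many questions in public health and spatial planning reduce to "how long
does it take to get there from everywhere?": travel time to the nearest
health facility, defibrillator, transit station or agricultural depot.
`timeraster` answers that for an arbitrary set of locations: given a
resistance **friction surface** — a raster whose cell values give the cost
of crossing the cell in minutes per metre — it produces a raster of the
same area where every cell holds the **minimum travel time in minutes to
the nearest of the supplied locations**.

## The method

The raster is treated as an 8-connected graph on its unmasked cells. The
edge between neighbouring cells $a$ and $b$ costs

$$w(a,b) = d(a,b)\,\frac{f_a+f_b}{2}\quad\text{minutes},$$

with $f$ the cell frictions (min/m) and $d$ the great-circle distance in
metres between the cell centers (haversine, sphere radius 6 371 008.8 m;
Euclidean map units on projected grids). A harmonic-mean variant
(`mean_conductance`), matching transition-matrix implementations, is also
available. The travel-time raster is the multi-source shortest-path
distance from all source cells at once, computed by a single Dijkstra pass
in C++. Source cells are exactly 0; cells disconnected from every source
(e.g. islands after land masking) are `+Inf`; masked cells stay nodata.

Supporting machinery: snapping arbitrary extents to the global 30
arc-second lattice used by the 2020 walking/motorised global friction
surfaces, cropping user rasters without resampling, polygon masking by cell
center, catchment allocation (`nearest_source_labels()`), synthetic
surface generation, single-band GeoTIFF read/write with an explicit nodata
contract, and a `prepare / compute / synth` command-line interface
(`exec/traveltime`). Named global surfaces are served through a pluggable
fetch adapter (`set_fetch_adapter()`), so the package itself never touches
the network.

## Worked example

Snapping the Singapore bounding box to the global 1/120° lattice:

```r
library(timeraster)
snap_extent(tt_extent(103.6091, 104.0858, 1.1664, 1.4714))
#> dimensions  : 37, 57 (nrow, ncol)
#> resolution  : 0.008333333, 0.008333333 (x, y)
#> extent      : 103.608333, 104.083333, 1.166667, 1.475000 (xmin, xmax, ymin, ymax) [geographic]
```

Each requested bound moved to the nearest lattice line, giving the 37 × 57
cell grid on which the walking friction surface for Singapore lives.

Walking time on a synthetic heterogeneous surface (random friction between
0.012 and 0.060 min/m — i.e. walking speeds between 5 and 1 km/h — over a
20 × 30 grid of 1/120° cells near the equator) from two "stations":

```r
set.seed(42)
surf <- synth_friction(20, 30, "random", base_value = 0.012, seed = 42)
stations <- data.frame(x = c(0.06, 0.19), y = c(0.05, 0.12))
tt <- calculate_travel_time(surf, stations)
tt
#> class       : tt_travel_time (minutes)
#> dimensions  : 20, 30 (nrow, ncol)
#> resolution  : 0.008333333, 0.008333333 (x, y)
#> extent      : 0.0000000, 0.2500000, 0.0000000, 0.1666667 (xmin, xmax, ymin, ymax) [geographic]
#> min value   : 0
#> max value   : 347.0291
#> edge model  : mean_friction, geodesic, 8-connected
#> sources     : 2 cell(s); unreachable cells: 0
```

The minimum is 0 (the station cells themselves); the farthest corner of
this surface is a 347-minute walk from the nearer station. The north-west
corner block, in minutes:

```r
round(tt$minutes[1:4, 1:5], 2)
#>        [,1]   [,2]   [,3]   [,4]   [,5]
#> [1,] 347.03 333.69 323.31 318.89 306.77
#> [2,] 335.00 302.92 301.86 319.63 285.43
#> [3,] 307.87 317.95 284.74 289.54 274.59
#> [4,] 277.90 270.85 259.28 256.83 263.09
```

Catchments — which station is nearest, per cell:

```r
table(nearest_source_labels(surf, stations)$labels)
#>   1   2
#> 310 290
```

`write_travel_time(tt, "minutes.tif")` writes a float32 GeoTIFF in which
unreachable and masked cells are the −9999 nodata sentinel, with their
counts and the edge model recorded in the file's metadata tag. The same
pipeline from a shell:

```sh
traveltime prepare --friction walking.tif --extent 103.6091,104.0858,1.1664,1.4714 \
           --mask singapore.geojson -o friction_sg.tif
traveltime compute --friction friction_sg.tif --points stations.csv -o minutes.tif --json
```

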