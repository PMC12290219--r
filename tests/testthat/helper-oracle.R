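# Independent oracles for the shortest-path engine. Everything here is
# deliberately written from first principles (own haversine, explicit edge
# enumeration, Bellman-Ford relaxation) so that it shares no code with the
# package's Dijkstra path.

EARTH_R <- 6371008.8

oracle_haversine <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_R * asin(pmin(1, sqrt(a)))
}

oracle_center <- function(grid, row, col) {
  c(grid$extent[["xmin"]] + (col - 0.5) * grid$resolution_x,
    grid$extent[["ymax"]] - (row - 0.5) * grid$resolution_y)
}

# Explicit directed edge list of the 8-connected unmasked graph.
oracle_edges <- function(surface, averaging = "mean_friction",
                         mode = c("geodesic", "planar")) {
  mode <- match.arg(mode)
  g <- surface$grid
  nr <- g$nrow; nc <- g$ncol
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (surface$mask[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (surface$mask[r2, c2]) next
      p1 <- oracle_center(g, r, c); p2 <- oracle_center(g, r2, c2)
      d <- if (mode == "geodesic") {
        oracle_haversine(p1[1], p1[2], p2[1], p2[2])
      } else {
        sqrt(sum((p1 - p2)^2))
      }
      fa <- surface$values[r, c]; fb <- surface$values[r2, c2]
      cost <- if (averaging == "mean_friction") d * (fa + fb) / 2
              else d / ((1 / fa + 1 / fb) / 2)
      from <- c(from, id(r, c)); to <- c(to, id(r2, c2)); w <- c(w, cost)
    }
  }
  list(from = from, to = to, w = w)
}

# Bellman-Ford: relax every edge until a full sweep changes nothing.
oracle_travel_time <- function(surface, src_row, src_col,
                               averaging = "mean_friction",
                               mode = "geodesic") {
  g <- surface$grid
  nr <- g$nrow; nc <- g$ncol
  e <- oracle_edges(surface, averaging, mode)
  dist <- rep(Inf, nr * nc)
  ok <- !surface$mask[cbind(src_row, src_col)]
  dist[(src_col[ok] - 1L) * nr + src_row[ok]] <- 0
  repeat {
    cand <- dist[e$from] + e$w
    best <- tapply(cand, e$to, min)
    idx <- as.integer(names(best))
    changed <- best < dist[idx] - 1e-15
    if (!any(changed)) break
    dist[idx[changed]] <- best[changed]
  }
  out <- matrix(dist, nr, nc)
  out[surface$mask] <- NA_real_
  out
}

random_test_surface <- function(nr, nc, mask_prob = 0.15, crs = "geographic") {
  vals <- matrix(exp(stats::runif(nr * nc, log(0.01), log(0.1))), nr, nc)
  mask <- matrix(stats::runif(nr * nc) < mask_prob, nr, nc)
  if (all(mask)) mask[1, 1] <- FALSE
  # away from the equator so cos-latitude shrinkage is exercised
  ext <- tt_extent(10, 10 + nc / 120, 40, 40 + nr / 120, crs = crs)
  friction_surface(vals, tt_grid(ext, 1 / 120), mask = mask)
}

# A source cell guaranteed unmasked, as center coordinates.
random_source_points <- function(surface, k = 1) {
  open <- which(!surface$mask, arr.ind = TRUE)
  pick <- open[sample.int(nrow(open), min(k, nrow(open))), , drop = FALSE]
  cell_center(surface$grid, pick[, 1], pick[, 2])
}

expect_minutes_equal <- function(engine, oracle, tol = 1e-9) {
  stopifnot(all(dim(engine) == dim(oracle)))
  both_na <- is.na(engine) & is.na(oracle)
  both_inf <- is.infinite(engine) & is.infinite(oracle)
  fin <- !both_na & !both_inf
  expect_true(all(is.finite(engine[fin]) & is.finite(oracle[fin])))
  denom <- pmax(1, abs(oracle[fin]))
  expect_lt(max(c(0, abs(engine[fin] - oracle[fin]) / denom)), tol)
}
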