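test_that("edge costs follow the two averaging rules", {
  # hand arithmetic at d = 1000 m: frictions 0.01 and 0.03 give
  # mean_friction 1000 * 0.02 = 20 min, mean_conductance 1000 / 66.67 = 15 min
  grid <- tt_grid(tt_extent(0, 2000, 0, 1000, crs = "planar"), 1000)
  surf <- friction_surface(matrix(c(0.01, 0.03), 1, 2), grid)
  expect_equal(edge_cost(surf, c(1, 1), c(1, 2)), 20)
  expect_equal(edge_cost(surf, c(1, 1), c(1, 2), edge_model("mean_conductance")),
               15)
  # symmetric in the two cells
  expect_equal(edge_cost(surf, c(1, 2), c(1, 1)), 20)

  # equal frictions make both averages coincide, on any distance mode
  u <- synth_friction(2, 2, "uniform", base_value = 0.02)
  for (avg in c("mean_friction", "mean_conductance")) {
    expect_equal(edge_cost(u, c(1, 1), c(1, 2), edge_model(avg)),
                 0.02 * great_circle_distance(cell_center(u$grid, 1, 1),
                                              cell_center(u$grid, 1, 2)))
  }

  eq <- synth_friction(1, 2, "uniform", base_value = 0.015,
                       extent = c(0, 2 / 120, -1 / 240, 1 / 240))
  expect_equal(edge_cost(eq, c(1, 1), c(1, 2)), 0.015 * 926.6257,
               tolerance = 1e-5)

  expect_error(edge_cost(u, c(1, 1), c(1, 1)), "8-neighbours")
  b <- synth_friction(5, 5, "corridor_with_barrier")
  expect_error(edge_cost(b, c(1, 2), c(1, 3)), "masked")
})

test_that("a 1x3 uniform equator strip accumulates one haversine step per cell", {
  surf <- synth_friction(1, 3, "uniform", base_value = 0.01,
                         extent = c(0, 3 / 120, -1 / 240, 1 / 240))
  tt <- calculate_travel_time(surf, cbind(x = 1 / 240, y = 0))
  step <- 0.01 * 6371008.8 * (pi / 180) / 120
  expect_equal(as.vector(tt$minutes), c(0, step, 2 * step), tolerance = 1e-9)
  expect_equal(as.vector(tt$minutes), c(0, 9.2663, 18.5326), tolerance = 1e-4)
})

test_that("source cells are zero and the minimum over the surface is zero", {
  set.seed(21)
  for (i in 1:5) {
    surf <- random_test_surface(sample(5:12, 1), sample(5:12, 1))
    pts <- random_source_points(surf, 3)
    tt <- calculate_travel_time(surf, pts)
    expect_identical(min(tt$minutes, na.rm = TRUE), 0)
    src <- source_set(pts, surf$grid)
    expect_true(all(tt$minutes[cbind(src$row, src$col)] == 0))
    expect_true(all(tt$minutes[!tt$mask] >= 0))
    expect_true(all(is.na(tt$minutes[tt$mask])))
  }
})

test_that("cells cut off by a barrier get infinite travel time", {
  surf <- synth_friction(5, 5, "corridor_with_barrier")
  west <- cell_center(surf$grid, 5, 1)
  tt <- calculate_travel_time(surf, west)
  expect_true(all(is.finite(tt$minutes[, 1:2])))
  expect_true(all(is.infinite(tt$minutes[, 4:5])))
  expect_true(all(is.na(tt$minutes[, 3])))
})

test_that("the engine agrees with a brute-force Bellman-Ford oracle", {
  set.seed(33)
  for (i in 1:25) {
    surf <- random_test_surface(sample(4:12, 1), sample(4:12, 1))
    avg <- sample(c("mean_friction", "mean_conductance"), 1)
    open <- which(!surf$mask, arr.ind = TRUE)
    pick <- open[sample.int(nrow(open), min(3, nrow(open))), , drop = FALSE]
    pts <- cell_center(surf$grid, pick[, 1], pick[, 2])
    tt <- calculate_travel_time(surf, pts, edge_model(avg))
    oracle <- oracle_travel_time(surf, pick[, 1], pick[, 2], avg)
    expect_minutes_equal(tt$minutes, oracle)
  }
})

test_that("multi-source equals the pointwise minimum of single-source runs", {
  set.seed(5)
  surf <- random_test_surface(10, 10)
  pts <- random_source_points(surf, 4)
  combined <- calculate_travel_time(surf, pts)$minutes
  singles <- lapply(seq_len(nrow(pts)), function(i) {
    calculate_travel_time(surf, pts[i, , drop = FALSE])$minutes
  })
  expect_equal(combined, Reduce(pmin, singles), tolerance = 1e-12)
})

test_that("results are deterministic and independent of source ordering", {
  set.seed(6)
  surf <- random_test_surface(9, 11)
  pts <- random_source_points(surf, 5)
  a <- calculate_travel_time(surf, pts)$minutes
  b <- calculate_travel_time(surf, pts[rev(seq_len(nrow(pts))), ])$minutes
  expect_identical(a, b)
})

test_that("adding a source never increases any cell's travel time", {
  set.seed(8)
  surf <- random_test_surface(10, 8)
  pts <- random_source_points(surf, 3)
  base <- calculate_travel_time(surf, pts[1:2, ])$minutes
  more <- calculate_travel_time(surf, pts)$minutes
  expect_true(all(more <= base + 1e-12, na.rm = TRUE))
})

test_that("raising one cell's friction never lowers any travel time", {
  set.seed(9)
  surf <- random_test_surface(8, 8, mask_prob = 0)
  pts <- random_source_points(surf, 2)
  before <- calculate_travel_time(surf, pts)$minutes
  v2 <- surf$values
  v2[4, 4] <- v2[4, 4] * 10
  after <- calculate_travel_time(friction_surface(v2, surf$grid), pts)$minutes
  expect_true(all(after >= before - 1e-12, na.rm = TRUE))
})

test_that("travel times scale linearly with friction", {
  set.seed(10)
  surf <- random_test_surface(7, 9)
  pts <- random_source_points(surf, 2)
  base <- calculate_travel_time(surf, pts)$minutes
  scaled <- calculate_travel_time(
    friction_surface(surf$values * 3.5, surf$grid, mask = surf$mask), pts
  )$minutes
  fin <- is.finite(base)
  expect_equal(scaled[fin], 3.5 * base[fin], tolerance = 1e-12)
  expect_identical(is.infinite(scaled), is.infinite(base))
})

test_that("uniform planar travel time matches the octile closed form", {
  s <- 100; f <- 0.02
  surf <- synth_friction(9, 9, "uniform", base_value = f, resolution = s,
                         extent = c(0, 900, 0, 900), crs = "planar")
  src <- c(5, 5)
  tt <- calculate_travel_time(surf, cell_center(surf$grid, src[1], src[2]))
  for (r in 1:9) for (c in 1:9) {
    dr <- abs(r - src[1]); dc <- abs(c - src[2])
    octile <- f * s * (sqrt(2) * min(dr, dc) + abs(dr - dc))
    expect_equal(tt$minutes[r, c], octile, tolerance = 1e-12)
  }
})

test_that("with symmetric edge costs the time between two cells is symmetric", {
  set.seed(12)
  surf <- random_test_surface(8, 8, mask_prob = 0.1)
  open <- which(!surf$mask, arr.ind = TRUE)
  ab <- open[sample.int(nrow(open), 2), ]
  t_ab <- calculate_travel_time(
    surf, cell_center(surf$grid, ab[2, 1], ab[2, 2]))$minutes[ab[1, 1], ab[1, 2]]
  t_ba <- calculate_travel_time(
    surf, cell_center(surf$grid, ab[1, 1], ab[1, 2]))$minutes[ab[2, 1], ab[2, 2]]
  expect_equal(t_ab, t_ba, tolerance = 1e-12)
})

test_that("nearest-source labels agree with per-source argmin and tie rules", {
  # single source: one label everywhere reachable
  surf <- synth_friction(4, 4, "uniform")
  lab1 <- nearest_source_labels(surf, cell_center(surf$grid, 2, 2))
  expect_true(all(lab1$labels == 1L))

  # symmetric strip: the midpoint ties and takes the lower index
  strip <- synth_friction(1, 5, "uniform")
  ends <- cell_center(strip$grid, c(1, 1), c(1, 5))
  lab <- nearest_source_labels(strip, ends)
  expect_identical(as.vector(lab$labels), c(1L, 1L, 1L, 2L, 2L))

  # random instance: labels achieve the minimum over single-source runs
  set.seed(14)
  rs <- random_test_surface(10, 10)
  pts <- random_source_points(rs, 4)
  lab4 <- nearest_source_labels(rs, pts)$labels
  singles <- lapply(seq_len(nrow(pts)), function(i) {
    calculate_travel_time(rs, pts[i, , drop = FALSE])$minutes
  })
  combined <- calculate_travel_time(rs, pts)$minutes
  for (cell in which(is.finite(combined))) {
    expect_equal(singles[[lab4[cell]]][cell], combined[cell],
                 tolerance = 1e-12)
  }
  # unreachable cells carry no label
  bar <- synth_friction(3, 5, "corridor_with_barrier")
  labbar <- nearest_source_labels(bar, cell_center(bar$grid, 1, 1))
  expect_true(all(is.na(labbar$labels[, 4:5])))
})

test_that("invalid source sets fail loudly or drop with a warning", {
  surf <- synth_friction(5, 5, "corridor_with_barrier")
  expect_error(calculate_travel_time(surf, cbind(x = numeric(0), y = numeric(0))),
               "empty|at least one")
  barrier_pt <- cell_center(surf$grid, 2, 3)
  expect_error(calculate_travel_time(surf, barrier_pt), "masked")
  outside <- cbind(x = 10, y = 10)
  expect_error(calculate_travel_time(surf, outside), "outside")
  mixed <- rbind(cell_center(surf$grid, 1, 1), outside)
  expect_warning(tt <- calculate_travel_time(surf, mixed, drop_bad_points = TRUE),
                 "dropped")
  expect_identical(tt$minutes[1, 1], 0)
  expect_error(
    suppressWarnings(calculate_travel_time(surf, outside, drop_bad_points = TRUE)),
    "all points")
})
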