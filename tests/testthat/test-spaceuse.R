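test_that("daily travel is the cumulative step length", {
  expect_equal(daily_travel(fix_tbl(x = c(0, 3, 3), y = c(0, 4, 4))), 5)
  expect_equal(daily_travel(fix_tbl(x = 0, y = 0)), 0)
  # square loop of side 10 returns to start but travel is 40
  loop <- fix_tbl(x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0),
                  by_min = 30)
  expect_equal(daily_travel(loop), 40)
  # travel dominates net displacement
  set.seed(41)
  rw <- fix_tbl(x = cumsum(rnorm(10)), y = cumsum(rnorm(10)), by_min = 30)
  net <- sqrt(diff(range(rw$x[c(1, 10)]))^2 + diff(rw$y[c(1, 10)])^2)
  expect_gte(daily_travel(rw), net)
})

test_that("daily travel rejects multi-day input", {
  fx <- fix_tbl(x = c(0, 1), y = c(0, 0), by_min = 60 * 30)
  expect_error(daily_travel(fx), "single calendar day")
})

test_that("MCP area matches the shoelace value and hull invariances", {
  sq <- fix_tbl(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(mcp_extent(sq)$area_m2, 1)
  # an interior point leaves the hull unchanged
  sq5 <- fix_tbl(x = c(0, 1, 1, 0, 0.5), y = c(0, 0, 1, 1, 0.5))
  expect_equal(mcp_extent(sq5)$area_m2, 1)
  # collinear fixes give a degenerate hull with zero area
  line <- fix_tbl(x = 0:3, y = 0:3)
  m <- mcp_extent(line)
  expect_equal(m$area_m2, 0)
  expect_true(m$degenerate)
})

test_that("MCP area is invariant under rigid motions", {
  set.seed(42)
  pts <- fix_tbl(x = rnorm(20), y = rnorm(20))
  a0 <- mcp_extent(pts)$area_m2
  th <- 0.83
  rot <- pts
  rot$x <- pts$x * cos(th) - pts$y * sin(th) + 12
  rot$y <- pts$x * sin(th) + pts$y * cos(th) - 7
  expect_equal(mcp_extent(rot)$area_m2, a0, tolerance = 1e-10)
})

test_that("MCP area equals the brute-force hull oracle on small sets", {
  set.seed(43)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    x <- runif(n) * 10
    y <- runif(n) * 10
    expect_equal(mcp_extent(fix_tbl(x = x, y = y))$area_m2,
                 oracle_hull_area(x, y), tolerance = 1e-9)
  }
})

test_that("extent distance equals the pairwise maximum", {
  expect_equal(extent_distance(fix_tbl(x = c(0, 30), y = c(0, 40))), 50)
  expect_equal(extent_distance(fix_tbl(x = rep(1, 4), y = rep(2, 4))), 0)
  expect_true(is.na(extent_distance(fix_tbl(x = 0, y = 0))))
  set.seed(44)
  x <- rnorm(100); y <- rnorm(100)
  d <- extent_distance(fix_tbl(x = x, y = y))
  expect_equal(d, oracle_max_dist(x, y), tolerance = 1e-12)
  # the diameter bounds every hull edge
  v <- mcp_extent(fix_tbl(x = x, y = y))$vertices
  edges <- sqrt(diff(c(v[, 1], v[1, 1]))^2 + diff(c(v[, 2], v[1, 2]))^2)
  expect_true(all(edges <= d + 1e-12))
})

test_that("plug-in bandwidth tracks the normal-reference rate", {
  set.seed(45)
  fx <- fix_tbl(x = rnorm(500), y = rnorm(500), by_min = 1)
  h <- plugin_bandwidth(fx)
  h_ref <- (4 / (3 * 500))^(1 / 5) # AMISE-optimal for unit-normal data
  expect_lt(abs(h[["hx"]] - h_ref) / h_ref, 0.25)
  expect_lt(abs(h[["hy"]] - h_ref) / h_ref, 0.25)

  # scale equivariance
  fx10 <- dplyr::mutate(fx, x = x * 10, y = y * 10)
  expect_equal(unname(plugin_bandwidth(fx10)), unname(h * 10),
               tolerance = 1e-6)

  # doubling the sample (each point twice) shrinks the bandwidth
  fx2 <- dplyr::bind_rows(fx, dplyr::mutate(fx, t = t + 1e6))
  expect_lt(plugin_bandwidth(fx2)[["hx"]], h[["hx"]])
})

test_that("degenerate samples are rejected with advice", {
  flat <- fix_tbl(x = rep(1, 20), y = rnorm(20))
  expect_error(plugin_bandwidth(flat), "zero variance")
  tiny <- fix_tbl(x = rnorm(5), y = rnorm(5))
  expect_error(plugin_bandwidth(tiny), "at least 8")
})

test_that("95% UD area approaches the bivariate-normal closed form", {
  set.seed(46)
  fx <- fix_tbl(x = rnorm(2000), y = rnorm(2000), by_min = 1)
  ud <- home_range_ud(fx)
  target <- pi * stats::qchisq(0.95, df = 2)
  expect_lt(abs(ud$area_m2 - target) / target, 0.15)
  expect_gt(length(ud$contours), 0)
})

test_that("UD area is monotone in the utilization level", {
  set.seed(47)
  fx <- fix_tbl(x = rnorm(300), y = rnorm(300), by_min = 1)
  a50 <- home_range_ud(fx, kde_config(ud_level = 0.50))$area_m2
  a95 <- home_range_ud(fx, kde_config(ud_level = 0.95))$area_m2
  a99 <- home_range_ud(fx, kde_config(ud_level = 0.99))$area_m2
  expect_lt(a50, a95)
  expect_lt(a95, a99)
})

test_that("well-separated clusters contribute additive UD area", {
  set.seed(48)
  one <- fix_tbl(x = rnorm(800), y = rnorm(800), by_min = 1)
  two <- dplyr::mutate(one, x = x + 40, t = t + 1e6)
  both <- dplyr::bind_rows(one, two)
  # fixed bandwidth isolates the mass-splitting logic from selection
  cfg1 <- kde_config(bandwidth_m = 0.35)
  cfg2 <- kde_config(bandwidth_m = 0.35, grid_cells = 512)
  a_one <- home_range_ud(one, cfg1)$area_m2
  a_both <- home_range_ud(both, cfg2)$area_m2
  expect_lt(abs(a_both - 2 * a_one) / (2 * a_one), 0.05)
})

test_that("percent difference follows the reporting convention", {
  expect_equal(percent_difference(2.53, 1), 153)
  expect_equal(percent_difference(3, 3), 0)
  expect_equal(percent_difference(0.44, 1), -56)
  expect_error(percent_difference(1, 0), "positive")
})

test_that("space-use summary applies the 7-day home-range rule", {
  set.seed(49)
  long_rp <- resident_params()
  sim_long <- simulate_resident(long_rp, n_days = 9, animal_id = "long")
  sim_short <- simulate_resident(long_rp, n_days = 3, animal_id = "short")
  fx <- dplyr::bind_rows(sim_long$fixes, sim_short$fixes)
  out <- space_use_summary(fx)
  expect_equal(nrow(out), 2)
  long_row <- out[out$animal_id == "long", ]
  short_row <- out[out$animal_id == "short", ]
  expect_false(is.na(long_row$home_range_m2))
  expect_true(is.na(short_row$home_range_m2))
  expect_gt(long_row$extent_area_m2, 0)
  expect_gte(long_row$extent_distance_m,
             sqrt(long_row$extent_area_m2 / pi)) # diameter beats disc radius
})
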