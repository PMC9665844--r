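release_noon <- as.POSIXct("2026-01-02 12:00:00", tz = "UTC")

test_that("homing success covers at least 70% of the distance in time", {
  # release (0,0), home centre (50,0): the 70% criterion is a 15-m approach
  rec_yes <- mk_record(c(10, 36), c(0, 0),
                       t = release_noon + c(1, 2) * 86400)
  expect_true(homing_success(rec_yes)) # 72% covered on day 2

  rec_no <- mk_record(c(10, 30), c(0, 0),
                      t = release_noon + c(1, 2) * 86400)
  expect_false(homing_success(rec_no)) # only 60%

  # reaching the centre exactly at the window end counts (inclusive)
  rec_edge <- mk_record(c(10, 50), c(0, 0),
                        t = release_noon + c(1, 3) * 86400)
  expect_true(homing_success(rec_edge))
  # ... but not after it
  rec_late <- mk_record(c(10, 50), c(0, 0),
                        t = release_noon + c(1, 3.01) * 86400)
  expect_false(homing_success(rec_late))
})

test_that("zero translocation distance is rejected", {
  rec <- mk_record(c(1, 2), c(0, 0), release = c(50, 0))
  expect_error(homing_success(rec), "coincides")
})

test_that("homing success is monotone in the homing fraction", {
  set.seed(51)
  home <- square_home(0, 0)
  hp <- homing_params()
  for (i in 1:20) {
    rec <- simulate_translocation(hp, home, "m")$record
    res <- vapply(c(0.5, 0.7, 0.9), function(f) {
      homing_success(rec, nav_config(homing_fraction = f))
    }, logical(1))
    expect_true(all(diff(res) <= 0)) # raising the bar only flips TRUE->FALSE
  }
})

test_that("explored area matches point-buffer and stadium closed forms", {
  one <- fix_tbl(x = 0, y = 0)
  expect_equal(explored_area(one), 25 * pi, tolerance = 0.005)

  seg <- fix_tbl(x = c(0, 100), y = c(0, 0), by_min = 20)
  expect_equal(explored_area(seg), 10 * 100 + 25 * pi, tolerance = 0.005)
})

test_that("explored area is a union: out-and-back equals one-way", {
  out_back <- fix_tbl(x = c(0, 50, 0), y = c(0, 0, 0), by_min = 30)
  one_way <- fix_tbl(x = c(0, 50), y = c(0, 0), by_min = 30)
  expect_equal(explored_area(out_back), explored_area(one_way))
})

test_that("explored area grows under added fixes and survives rigid motion", {
  base <- fix_tbl(x = c(0, 20), y = c(0, 0), by_min = 30)
  more <- fix_tbl(x = c(0, 20, 40), y = c(0, 0, 30), by_min = 30)
  expect_gt(explored_area(more), explored_area(base))

  th <- 1.1
  rot <- base
  rot$x <- base$x * cos(th) - base$y * sin(th) + 100
  rot$y <- base$x * sin(th) + base$y * cos(th) - 50
  expect_equal(explored_area(rot), explored_area(base), tolerance = 0.01)
})

test_that("straightness is net displacement over path length", {
  # straight path release -> home is perfectly direct
  rec <- mk_record(c(10, 25, 36), c(0, 0, 0),
                   t = release_noon + c(1, 2, 3) * 3600)
  expect_equal(straightness(rec), 1)

  # (0,0) -> (3,4) -> (6,0): net 6, path 10; home far away, no truncation
  far_home <- square_home(1000, 0)
  rec2 <- mk_record(c(3, 6), c(4, 0), home = far_home,
                    t = release_noon + c(1, 2) * 3600)
  expect_equal(straightness(rec2), 0.6)

  # a repeated (zero-length) fix changes nothing
  rec3 <- mk_record(c(3, 3, 6), c(4, 4, 0), home = far_home,
                    t = release_noon + c(1, 2, 3) * 3600)
  expect_equal(straightness(rec3), 0.6)
})

test_that("straightness truncates at the buffered home polygon", {
  # fix inside the 10-m home buffer, then wandering afterwards: the
  # post-arrival fixes must not dilute the ratio
  arrive <- mk_record(c(20, 42, 42, 20), c(0, 0, 30, 50),
                      t = release_noon + c(1, 2, 3, 4) * 3600)
  expect_equal(straightness(arrive), 1)
})

test_that("angular deviation reads the first band crossing", {
  # d50 band is the [5, 15] m annulus around the release site
  east <- mk_record(c(12, 30), c(0, 0))
  expect_equal(as.numeric(angular_deviation(east)), 0)

  north <- mk_record(c(0, 0), c(12, 30))
  expect_equal(as.numeric(angular_deviation(north)), pi / 2)

  # stationary frog never reaches the band's lower bound
  stay <- mk_record(c(1, 2, 1), c(0, 1, -1))
  expect_true(is.na(angular_deviation(stay)))
})

test_that("band jumps are interpolated at the centre radius", {
  # one step from 2 m to 30 m crosses the whole [5, 15] band: the crossing
  # is read on the segment at radius 10
  jump <- mk_record(c(2, 30), c(2, 30))
  dev <- angular_deviation(jump)
  expect_equal(as.numeric(dev), pi / 4)
  expect_true(attr(dev, "interpolated"))

  # interp mode always uses the interpolated centre-radius crossing
  east <- mk_record(c(12, 30), c(0, 0))
  dev2 <- angular_deviation(east, nav_config(band_mode = "interp"))
  expect_equal(as.numeric(dev2), 0)
  expect_true(attr(dev2, "interpolated"))
})

test_that("angular deviation is antisymmetric under reflection", {
  set.seed(52)
  for (i in 1:10) {
    xs <- cumsum(runif(6, 0, 8))
    ys <- cumsum(rnorm(6, sd = 4))
    rec <- mk_record(xs, ys)
    mir <- mk_record(xs, -ys)
    d1 <- as.numeric(angular_deviation(rec))
    d2 <- as.numeric(angular_deviation(mir))
    if (is.na(d1)) {
      expect_true(is.na(d2))
    } else {
      expect_equal(d2, -d1, tolerance = 1e-12)
    }
  }
})

test_that("homing duration excludes 12-h nights", {
  # release noon day 1, buffer entry noon day 2: one full night excluded
  overnight <- mk_record(c(20, 39), c(0, 0),
                         t = release_noon + c(23, 24) * 3600)
  expect_equal(homing_duration(overnight), 12)

  # entry 2 h after release the same day
  same_day <- mk_record(c(20, 39), c(0, 0),
                        t = release_noon + c(1, 2) * 3600)
  expect_equal(homing_duration(same_day), 2)

  # entry at 20:00 counts only up to nightfall (18:00)
  dusk <- mk_record(c(20, 39), c(0, 0),
                    t = release_noon + c(6, 8) * 3600)
  expect_equal(homing_duration(dusk), 6)
})

test_that("buffer entry time is interpolated along the entering step", {
  # step from 29 m outside the buffer to 1 m inside it, over 1 h: the
  # boundary (x = 39) is crossed at 29/30 of the step
  rec <- mk_record(c(10, 40), c(0, 0),
                   t = release_noon + c(1, 2) * 3600)
  expect_equal(homing_duration(rec), 1 + 29 / 30, tolerance = 1e-6)
})

test_that("homing duration demands a buffer entry", {
  never <- mk_record(c(10, 20), c(0, 0))
  expect_error(homing_duration(never), "inconsistent")
})

test_that("homeward normalization maps release to origin and home up", {
  rec <- mk_record(c(0, 50), c(0, 0), t = release_noon + c(1, 2) * 3600)
  norm <- normalize_homeward(rec)
  expect_equal(norm$x, c(0, 0), tolerance = 1e-12)
  expect_equal(norm$y, c(0, 50), tolerance = 1e-12)
  expect_equal(unname(attr(norm, "home")), c(0, 50))
})

test_that("homeward normalization is an isometry", {
  set.seed(53)
  xs <- rnorm(8, 20, 10); ys <- rnorm(8, 5, 10)
  rec <- mk_record(xs, ys, home = square_home(30, 40))
  norm <- normalize_homeward(rec)
  d_before <- dist(cbind(xs, ys))
  d_after <- dist(cbind(norm$x, norm$y))
  expect_equal(as.vector(d_after), as.vector(d_before), tolerance = 1e-10)
})

test_that("nav_summary assembles per-animal metrics with NA rules", {
  set.seed(54)
  home <- square_home(0, 0)
  recs <- list(
    simulate_translocation(beeline_params(), home, "beeline")$record,
    simulate_translocation(stay_params(), home, "stay")$record
  )
  out <- nav_summary(recs)
  expect_equal(out$animal_id, c("beeline", "stay"))
  expect_equal(out$homing, c(TRUE, FALSE))
  expect_true(is.na(out$straightness[2]))
  expect_true(is.na(out$homing_duration_h[2]))
  expect_false(is.na(out$explored_area_m2[1]))
})
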