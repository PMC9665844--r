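#' Navigation analysis configuration
#'
#' Parameters of the translocation-experiment metrics. Defaults follow the
#' field protocol: homing means covering at least 70% of the release-to-home
#' distance within the class-specific window; explored area uses a 5-m
#' perceptual-range buffer on the 15-min downsampled track; initial
#' orientation is read where the track first crosses a 10 +/- 5 m (50-m
#' translocations) or 40 +/- 20 m (200-m translocations) radius band around
#' the release site (~20% of the translocation distance); homing duration
#' ends at a 10-m buffer around the home polygon and excludes 12-h nights
#' (18:00-06:00).
#'
#' @param homing_fraction Fraction of the translocation distance that must
#'   be covered for homing (default 0.70).
#' @param perceptual_radius_m Perceptual-range buffer radius in metres.
#' @param nav_min_interval_min Downsampling interval for explored area and
#'   straightness, minutes.
#' @param band_d50,band_d200 Named vectors `c(center =, halfwidth =)` in
#'   metres defining the orientation band per translocation class.
#' @param home_buffer_m Buffer around the home polygon ending the homing
#'   clock.
#' @param night_start,night_end Hours of day bounding the excluded night.
#' @param band_mode `"fix"` (first fix inside the band; a step jumping the
#'   whole band is interpolated at the centre radius) or `"interp"` (always
#'   interpolate the first crossing of the centre radius).
#' @param cell_m Raster cell size for the explored-area computation, metres.
#' @return A list of class `nav_config`.
#' @export
nav_config <- function(homing_fraction = 0.70,
                       perceptual_radius_m = 5,
                       nav_min_interval_min = 15,
                       band_d50 = c(center = 10, halfwidth = 5),
                       band_d200 = c(center = 40, halfwidth = 20),
                       home_buffer_m = 10,
                       night_start = 18, night_end = 6,
                       band_mode = c("fix", "interp"),
                       cell_m = 0.25) {
  band_mode <- match.arg(band_mode)
  stopifnot(homing_fraction > 0, homing_fraction < 1,
            perceptual_radius_m > 0, cell_m > 0,
            band_d50[["halfwidth"]] < band_d50[["center"]],
            band_d200[["halfwidth"]] < band_d200[["center"]])
  structure(
    list(homing_fraction = homing_fraction,
         perceptual_radius_m = perceptual_radius_m,
         nav_min_interval_min = nav_min_interval_min,
         band_d50 = band_d50, band_d200 = band_d200,
         home_buffer_m = home_buffer_m,
         night_start = night_start, night_end = night_end,
         band_mode = band_mode, cell_m = cell_m),
    class = "nav_config"
  )
}

#' Home area of a translocated animal
#'
#' The set of fixes recorded before translocation, their convex hull, and
#' the home centre defined as the geometric average (coordinate-wise
#' arithmetic mean) of the pre-translocation positions.
#'
#' @param fixes Fix tibble of pre-translocation positions (>= 1 fix).
#' @return An object of class `frog_home`: list with `center` (length-2),
#'   `vertices` (hull matrix), `fixes`.
#' @export
home_area <- function(fixes) {
  fixes <- as_fixes(fixes)
  if (nrow(fixes) == 0) abort("home area needs at least one fix")
  structure(
    list(center = c(x = mean(fixes$x), y = mean(fixes$y)),
         vertices = hull_vertices(fixes$x, fixes$y),
         fixes = fixes),
    class = "frog_home"
  )
}

#' @export
print.frog_home <- function(x, ...) {
  cat("<frog_home> center (", paste(signif(x$center, 5), collapse = ", "),
      "), ", nrow(x$fixes), " fixes\n", sep = "")
  invisible(x)
}

#' Build a translocation record
#'
#' Bundles one translocation event: the release point and time, the distance
#' class (`d50` = ~50 m with a 3-day homing window, `d200` = ~200 m with a
#' 6-day window), the animal's home area, and the tracked post-release
#' trajectory.
#'
#' @param animal_id Animal identifier.
#' @param release_point Length-2 numeric release coordinates.
#' @param release_time POSIXct release time.
#' @param distance_class `"d50"` or `"d200"`.
#' @param home A [home_area()] object.
#' @param track Fix tibble of post-release fixes (first at/after release).
#' @return An object of class `frog_transloc`.
#' @export
translocation_record <- function(animal_id, release_point, release_time,
                                 distance_class = c("d50", "d200"),
                                 home, track) {
  distance_class <- match.arg(distance_class)
  stopifnot(inherits(home, "frog_home"), length(release_point) == 2)
  track <- as_fixes(track)
  if (nrow(track) == 0) abort("translocation track is empty")
  if (min(track$t) < release_time) {
    abort("track contains fixes before the release time")
  }
  structure(
    list(animal_id = animal_id,
         release_point = c(x = release_point[[1]], y = release_point[[2]]),
         release_time = release_time,
         distance_class = distance_class,
         window_days = if (distance_class == "d50") 3L else 6L,
         home = home,
         track = track),
    class = "frog_transloc"
  )
}

#' @export
print.frog_transloc <- function(x, ...) {
  cat("<frog_transloc> ", x$animal_id, " ", x$distance_class, " (",
      x$window_days, "-day window), ", nrow(x$track), " fixes\n", sep = "")
  invisible(x)
}

transloc_distance <- function(rec) {
  d <- dist2d(rec$release_point, rec$home$center)
  if (d == 0) abort("release point coincides with the home center")
  d
}

#' Homing success
#'
#' `TRUE` when the animal approached within `(1 - homing_fraction)` of the
#' release-to-home-centre distance (i.e. covered at least 70% of it by
#' default) within the class-specific window (3 or 6 days, counted as 24-h
#' periods from release). Evaluated on the full-resolution track; both the
#' distance and time boundaries are inclusive.
#'
#' @param rec A [translocation_record()].
#' @param cfg A [nav_config()].
#' @return Logical.
#' @export
homing_success <- function(rec, cfg = nav_config()) {
  d0 <- transloc_distance(rec)
  deadline <- rec$release_time + rec$window_days * 86400
  tr <- rec$track[rec$track$t <= deadline, ]
  if (nrow(tr) == 0) return(FALSE)
  dd <- sqrt((tr$x - rec$home$center[["x"]])^2 +
               (tr$y - rec$home$center[["y"]])^2)
  any(dd <= (1 - cfg$homing_fraction) * d0)
}

# Area of the union of r-buffers around the vertices and segments of a path,
# by a rasterised distance field with linear sub-cell coverage correction.
buffer_union_area <- function(x, y, r, cell = 0.25, max_cells = 4e7) {
  stopifnot(length(x) >= 1, r > 0)
  pad <- r + 2 * cell
  gx <- seq(min(x) - pad, max(x) + pad, by = cell)
  gy <- seq(min(y) - pad, max(y) + pad, by = cell)
  while (length(gx) * length(gy) > max_cells) {
    cell <- cell * 2
    gx <- seq(min(x) - pad, max(x) + pad, by = cell)
    gy <- seq(min(y) - pad, max(y) + pad, by = cell)
  }
  dmin <- matrix(Inf, nrow = length(gx), ncol = length(gy))
  seg_from <- if (length(x) > 1) seq_len(length(x) - 1) else 1L
  for (i in seg_from) {
    j <- min(i + 1, length(x))
    # restrict the update to the sub-window covering this segment's buffer
    xr <- range(x[i], x[j])
    yr <- range(y[i], y[j])
    ix <- which(gx >= xr[1] - pad & gx <= xr[2] + pad)
    iy <- which(gy >= yr[1] - pad & gy <= yr[2] + pad)
    if (length(ix) == 0 || length(iy) == 0) next
    px <- rep(gx[ix], times = length(iy))
    py <- rep(gy[iy], each = length(ix))
    d <- point_segment_dist(px, py, x[i], y[i], x[j], y[j])
    sub <- dmin[ix, iy]
    dmin[ix, iy] <- pmin(sub, matrix(d, nrow = length(ix)))
  }
  coverage <- pmin(1, pmax(0, (r - dmin) / cell + 0.5))
  sum(coverage) * cell^2
}

#' Explored area around a trajectory
#'
#' Total area within the perceptual radius (default 5 m, the putative
#' perceptual range of a frog) of the movement trajectory: the union of
#' round-capped buffers around every segment and vertex of the track, after
#' downsampling to the navigation minimum interval. A single fix gives
#' `pi * r^2`. Computed on a fine raster with sub-cell coverage correction;
#' `cfg$cell_m` controls the resolution.
#'
#' @param track Fix tibble of post-release fixes (or a
#'   [translocation_record()], whose track is used).
#' @param cfg A [nav_config()].
#' @return Area in square metres.
#' @export
explored_area <- function(track, cfg = nav_config()) {
  if (inherits(track, "frog_transloc")) track <- track$track
  track <- nav_downsample(track, cfg$nav_min_interval_min)
  r <- cfg$perceptual_radius_m
  if (nrow(track) == 1) return(pi * r^2)
  buffer_union_area(track$x, track$y, r, cell = cfg$cell_m)
}

# distance from a point to the home polygon (0 inside)
home_poly_dist <- function(p, home) {
  dist_to_convex(p, home$vertices[, 1], home$vertices[, 2])
}

# index of first track fix inside the buffered home polygon, NA if none
first_buffer_entry <- function(rec, cfg) {
  dd <- vapply(seq_len(nrow(rec$track)), function(i) {
    home_poly_dist(c(rec$track$x[i], rec$track$y[i]), rec$home)
  }, numeric(1))
  idx <- which(dd <= cfg$home_buffer_m)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Homing trajectory straightness
#'
#' Ratio between the straight-line distance from the release site to the end
#' of the homing trajectory and the cumulative length of the actual homing
#' trajectory, in (0, 1]; 1 means a perfectly direct return. The track is
#' downsampled to the navigation minimum interval and truncated at the first
#' fix inside the buffered home polygon, so the "end" is the arrival point,
#' not post-arrival wandering. Only defined for homing animals.
#'
#' @param rec A [translocation_record()] with `homing_success()` true.
#' @param cfg A [nav_config()].
#' @return Straightness in (0, 1], or `NA` when the path length is zero.
#' @export
straightness <- function(rec, cfg = nav_config()) {
  tr <- nav_downsample(rec$track, cfg$nav_min_interval_min)
  idx <- NA_integer_
  dd <- vapply(seq_len(nrow(tr)), function(i) {
    home_poly_dist(c(tr$x[i], tr$y[i]), rec$home)
  }, numeric(1))
  inside <- which(dd <= cfg$home_buffer_m)
  if (length(inside) > 0) {
    tr <- tr[seq_len(inside[1]), ]
  }
  px <- c(rec$release_point[["x"]], tr$x)
  py <- c(rec$release_point[["y"]], tr$y)
  total <- path_length(px, py)
  if (total == 0) return(NA_real_)
  net <- dist2d(c(px[1], py[1]), c(px[length(px)], py[length(py)]))
  net / total
}

#' Angular deviation from the home direction
#'
#' Signed difference (radians, in (-pi, pi]) between the bearing from the
#' release site to the point where the track first crosses the orientation
#' band and the bearing from the release site to the home centre. Positive
#' values are counter-clockwise of home. In `"fix"` mode (default) the first
#' fix whose distance from the release site lies inside the band is used;
#' when a single step jumps across the whole band, the crossing is linearly
#' interpolated at the band's centre radius. In `"interp"` mode the first
#' interpolated crossing of the centre radius is always used. `NA` when the
#' animal never reaches the band's lower bound.
#'
#' @param rec A [translocation_record()].
#' @param cfg A [nav_config()].
#' @return Signed angle in radians, or `NA`. The attribute `interpolated`
#'   marks band-jump interpolation.
#' @export
angular_deviation <- function(rec, cfg = nav_config()) {
  band <- if (rec$distance_class == "d50") cfg$band_d50 else cfg$band_d200
  lo <- band[["center"]] - band[["halfwidth"]]
  hi <- band[["center"]] + band[["halfwidth"]]
  rel <- c(rec$release_point[["x"]], rec$release_point[["y"]])
  d <- sqrt((rec$track$x - rel[1])^2 + (rec$track$y - rel[2])^2)
  pt <- NULL
  interpolated <- FALSE
  if (cfg$band_mode == "fix") {
    for (i in seq_along(d)) {
      if (d[i] >= lo && d[i] <= hi) {
        pt <- c(rec$track$x[i], rec$track$y[i])
        break
      }
      if (d[i] > hi) {
        # the step from i-1 jumped across the whole band: interpolate the
        # crossing of the centre radius along that step
        prev <- if (i == 1) rel else c(rec$track$x[i - 1], rec$track$y[i - 1])
        pt <- interp_radius_crossing(rel, prev, c(rec$track$x[i],
                                                  rec$track$y[i]),
                                     band[["center"]])
        interpolated <- TRUE
        break
      }
    }
  } else {
    for (i in seq_along(d)) {
      if (d[i] >= band[["center"]]) {
        prev <- if (i == 1) rel else c(rec$track$x[i - 1], rec$track$y[i - 1])
        pt <- interp_radius_crossing(rel, prev, c(rec$track$x[i],
                                                  rec$track$y[i]),
                                     band[["center"]])
        interpolated <- TRUE
        break
      }
    }
  }
  if (is.null(pt)) return(NA_real_)
  dev <- wrap_pi(bearing(rel, pt) -
                   bearing(rel, c(rec$home$center[["x"]],
                                  rec$home$center[["y"]])))
  attr(dev, "interpolated") <- interpolated
  dev
}

# first point on segment a -> b at distance `radius` from the origin `rel`
interp_radius_crossing <- function(rel, a, b, radius) {
  f <- function(s) {
    p <- a + s * (b - a)
    sqrt(sum((p - rel)^2)) - radius
  }
  if (f(0) >= 0) return(a)
  s <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
  a + s * (b - a)
}

#' Homing duration with nights excluded
#'
#' Time from release to the moment the animal crossed a buffer (default
#' 10 m) around the home-area polygon, with nighttime excluded: the study
#' species do not move at night, so only the overlap of the release-to-entry
#' interval with the daytime windows (06:00-18:00 by default, i.e. 12-h
#' nights) is counted. The entering step is linearly interpolated against
#' the buffer boundary.
#'
#' @param rec A [translocation_record()] with `homing_success()` true.
#' @param cfg A [nav_config()].
#' @return Duration in hours (>= 0).
#' @export
homing_duration <- function(rec, cfg = nav_config()) {
  idx <- first_buffer_entry(rec, cfg)
  if (is.na(idx)) {
    abort("no fix inside the buffered home polygon; inputs inconsistent")
  }
  entry_time <- rec$track$t[idx]
  if (idx > 1) {
    a <- c(rec$track$x[idx - 1], rec$track$y[idx - 1])
    b <- c(rec$track$x[idx], rec$track$y[idx])
    da <- home_poly_dist(a, rec$home)
    if (da > cfg$home_buffer_m) {
      f <- function(s) {
        home_poly_dist(a + s * (b - a), rec$home) - cfg$home_buffer_m
      }
      s <- stats::uniroot(f, c(0, 1), tol = 1e-10)$root
      entry_time <- rec$track$t[idx - 1] +
        s * as.numeric(difftime(rec$track$t[idx], rec$track$t[idx - 1],
                                units = "secs"))
    }
  }
  daytime_overlap_hours(rec$release_time, entry_time,
                        day_start = cfg$night_end,
                        day_end = cfg$night_start)
}

#' Normalize a translocation track to the homeward frame
#'
#' Rigid motion mapping the release site to the origin and the home
#' direction to "up" (+y), so trajectories of different animals overlay with
#' a common start and home direction. Distances are preserved.
#'
#' @param rec A [translocation_record()].
#' @return The track tibble with transformed `x`, `y`; the attribute `home`
#'   holds the transformed home centre `(0, D)`.
#' @export
normalize_homeward <- function(rec) {
  rel <- c(rec$release_point[["x"]], rec$release_point[["y"]])
  ctr <- c(rec$home$center[["x"]], rec$home$center[["y"]])
  d0 <- transloc_distance(rec)
  theta <- bearing(rel, ctr)
  rot <- pi / 2 - theta
  xs <- rec$track$x - rel[1]
  ys <- rec$track$y - rel[2]
  out <- rec$track
  out$x <- xs * cos(rot) - ys * sin(rot)
  out$y <- xs * sin(rot) + ys * cos(rot)
  attr(out, "home") <- c(x = 0, y = d0)
  out
}

#' Per-animal navigation summary
#'
#' Applies all navigation metrics to a list of translocation records and
#' returns the model-ready tidy table. Straightness and homing duration are
#' defined only for homing animals; angular deviation only when the track
#' reaches the orientation band. `log`-transformed exports of spatial
#' variables downstream use the natural logarithm.
#'
#' @param recs A list of [translocation_record()] objects.
#' @param cfg A [nav_config()].
#' @return A tibble with one row per record: `animal_id`, `distance_class`,
#'   `homing`, `explored_area_m2`, `straightness`, `angular_deviation_rad`,
#'   `homing_duration_h`.
#' @export
nav_summary <- function(recs, cfg = nav_config()) {
  if (inherits(recs, "frog_transloc")) recs <- list(recs)
  purrr::map_dfr(recs, function(rec) {
    homing <- homing_success(rec, cfg)
    tibble::tibble(
      animal_id = rec$animal_id,
      distance_class = rec$distance_class,
      homing = homing,
      explored_area_m2 = explored_area(rec, cfg),
      straightness = if (homing) straightness(rec, cfg) else NA_real_,
      angular_deviation_rad = as.numeric(angular_deviation(rec, cfg)),
      homing_duration_h = if (homing && !is.na(first_buffer_entry(rec, cfg)))
        homing_duration(rec, cfg) else NA_real_
    )
  })
}
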