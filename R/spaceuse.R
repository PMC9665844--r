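#' Daily cumulative travel distance
#'
#' Sum of Euclidean step lengths between consecutive fixes of one animal on
#' one calendar day. A single fix gives 0; a closed loop gives the full loop
#' length (travel is path length, not net displacement).
#'
#' @param fixes Fix tibble for a single animal and a single calendar day.
#' @return Distance in metres.
#' @export
daily_travel <- function(fixes) {
  fixes <- as_fixes(fixes)
  if (length(unique(fixes$animal_id)) > 1) {
    abort("daily_travel() expects fixes of a single animal")
  }
  if (length(unique(local_date(fixes$t))) > 1) {
    abort("daily_travel() expects fixes of a single calendar day")
  }
  path_length(fixes$x, fixes$y)
}

#' Movement extent as a minimum convex polygon
#'
#' Convex hull of 100% of an animal's fixes with its shoelace area: a proxy
#' for the full extent of the area explored, including rare excursions.
#' Collinear or duplicate point sets give a degenerate hull with area 0.
#'
#' @param fixes Fix tibble (or any data frame with `x`, `y`).
#' @return An object of class `frog_mcp`: list with `vertices` (CCW n-by-2
#'   matrix), `area_m2`, `degenerate`, `n`.
#' @examples
#' sq <- tibble::tibble(animal_id = "f", t = Sys.time() + 1:4,
#'                      x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
#' mcp_extent(sq)$area_m2 # 1
#' @export
mcp_extent <- function(fixes) {
  stopifnot(all(c("x", "y") %in% names(fixes)))
  v <- hull_vertices(fixes$x, fixes$y)
  area <- shoelace_area(v[, 1], v[, 2])
  structure(
    list(vertices = v, area_m2 = area,
         degenerate = nrow(v) < 3 || area == 0, n = nrow(fixes)),
    class = "frog_mcp"
  )
}

#' @export
print.frog_mcp <- function(x, ...) {
  cat("<frog_mcp> area:", format(x$area_m2), "m^2,",
      nrow(x$vertices), "hull vertices",
      if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' @rdname mcp_extent
#' @param x A `frog_mcp` object.
#' @param ... Unused.
#' @export
tidy.frog_mcp <- function(x, ...) {
  tibble::tibble(vertex = seq_len(nrow(x$vertices)),
                 x = x$vertices[, 1], y = x$vertices[, 2])
}

#' @rdname mcp_extent
#' @export
glance.frog_mcp <- function(x, ...) {
  tibble::tibble(area_m2 = x$area_m2, n = x$n, degenerate = x$degenerate)
}

#' Movement extent as a maximum linear distance
#'
#' Maximum pairwise Euclidean distance between all locations of one animal
#' (the diameter of the fix set). Computed over convex-hull vertices, which
#' carry the diameter; equals the brute-force pairwise maximum.
#'
#' @param fixes Fix tibble (or any data frame with `x`, `y`).
#' @return Distance in metres; `NA` for fewer than 2 fixes.
#' @export
extent_distance <- function(fixes) {
  stopifnot(all(c("x", "y") %in% names(fixes)))
  if (nrow(fixes) < 2) return(NA_real_)
  v <- hull_vertices(fixes$x, fixes$y)
  if (nrow(v) < 2) return(0)
  max_pairwise_dist(v[, 1], v[, 2])
}

#' Per-axis plug-in bandwidth for the kernel UD
#'
#' Two-stage direct plug-in bandwidth (Sheather-Jones/Wand-Jones family) for
#' a Gaussian kernel, computed independently per axis via
#' [stats::bw.SJ()] with `method = "dpi"`. This is the conservative
#' data-driven selector used for utilization-distribution smoothing.
#'
#' @param fixes Fix tibble or data frame with `x`, `y` (n >= 8).
#' @return Named numeric vector `c(hx, hy)` in metres, both positive.
#' @export
plugin_bandwidth <- function(fixes) {
  stopifnot(all(c("x", "y") %in% names(fixes)))
  if (nrow(fixes) < 8) {
    abort("plug-in bandwidth needs at least 8 fixes")
  }
  if (stats::sd(fixes$x) == 0 || stats::sd(fixes$y) == 0) {
    abort(paste0("zero variance on one axis: jitter the fixes or report ",
                 "MCP extent only"))
  }
  c(hx = stats::bw.SJ(fixes$x, method = "dpi"),
    hy = stats::bw.SJ(fixes$y, method = "dpi"))
}

silverman_bandwidth <- function(fixes) {
  c(hx = stats::bw.nrd0(fixes$x), hy = stats::bw.nrd0(fixes$y))
}

#' Kernel utilization-distribution configuration
#'
#' @param bandwidth Bandwidth selector: `"plugin"` (two-stage direct
#'   plug-in, the default) or `"silverman"` (normal reference rule).
#' @param grid_cells Grid cells per axis (>= 64).
#' @param grid_pad Grid padding beyond the fix bounding box, in multiples of
#'   the larger bandwidth.
#' @param ud_level Utilization level of the home-range contour, in (0, 1).
#' @param bandwidth_m Optional fixed bandwidth in metres (scalar or
#'   `c(hx, hy)`), overriding the selector; intended for sensitivity
#'   analyses.
#' @return A list of class `kde_config`.
#' @export
kde_config <- function(bandwidth = c("plugin", "silverman"),
                       grid_cells = 256, grid_pad = 3, ud_level = 0.95,
                       bandwidth_m = NULL) {
  bandwidth <- match.arg(bandwidth)
  stopifnot(ud_level > 0, ud_level < 1, grid_cells >= 64, grid_pad > 0)
  if (!is.null(bandwidth_m)) {
    stopifnot(all(bandwidth_m > 0), length(bandwidth_m) %in% 1:2)
    bandwidth_m <- rep(bandwidth_m, length.out = 2)
  }
  structure(list(bandwidth = bandwidth, grid_cells = grid_cells,
                 grid_pad = grid_pad, ud_level = ud_level,
                 bandwidth_m = bandwidth_m),
            class = "kde_config")
}

#' Home range as a kernel utilization-distribution contour
#'
#' Estimates the utilization distribution with a Gaussian product kernel on
#' a padded regular grid and reports the area of the smallest superlevel set
#' holding `ud_level` of the total grid mass (default 95%): the area the
#' animal uses routinely, excluding rare excursions. Area is grid-based
#' (cells above threshold times cell area); contour polygons at the
#' threshold density are attached for mapping.
#'
#' @param fixes Fix tibble for one animal (n >= 8).
#' @param cfg A [kde_config()].
#' @return An object of class `frog_ud`: list with `area_m2`, `ud_level`,
#'   `threshold` (density at the contour), `h` (bandwidths), `n`, `grid_x`,
#'   `grid_y`, `density` (matrix, x by y), and `contours` (list of
#'   data frames with `x`, `y`).
#' @export
home_range_ud <- function(fixes, cfg = kde_config()) {
  stopifnot(all(c("x", "y") %in% names(fixes)))
  n <- nrow(fixes)
  if (n < 8) abort("kernel home range needs at least 8 fixes")
  h <- if (!is.null(cfg$bandwidth_m)) {
    c(hx = cfg$bandwidth_m[1], hy = cfg$bandwidth_m[2])
  } else {
    switch(cfg$bandwidth,
           plugin = plugin_bandwidth(fixes),
           silverman = silverman_bandwidth(fixes))
  }
  pad <- cfg$grid_pad * max(h)
  gx <- seq(min(fixes$x) - pad, max(fixes$x) + pad,
            length.out = cfg$grid_cells)
  gy <- seq(min(fixes$y) - pad, max(fixes$y) + pad,
            length.out = cfg$grid_cells)
  # f(x, y) = (1/n) sum_i phi_hx(x - xi) phi_hy(y - yi), factorised into a
  # matrix product over the grid
  kx <- stats::dnorm(outer(gx, fixes$x, "-"), sd = h[["hx"]])
  ky <- stats::dnorm(outer(gy, fixes$y, "-"), sd = h[["hy"]])
  dens <- (kx %*% t(ky)) / n
  cell_area <- diff(gx[1:2]) * diff(gy[1:2])
  mass <- dens / sum(dens)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= cfg$ud_level)[1]
  threshold <- dens[ord[k]]
  area <- k * cell_area
  contours <- grDevices::contourLines(gx, gy, dens, levels = threshold)
  contours <- lapply(contours, function(cl) data.frame(x = cl$x, y = cl$y))
  structure(
    list(area_m2 = area, ud_level = cfg$ud_level, threshold = threshold,
         h = h, n = n, grid_x = gx, grid_y = gy, density = dens,
         contours = contours),
    class = "frog_ud"
  )
}

#' @export
print.frog_ud <- function(x, ...) {
  cat("<frog_ud> ", round(100 * x$ud_level), "% UD area: ",
      format(x$area_m2), " m^2 (n = ", x$n, ", h = ",
      paste(signif(x$h, 3), collapse = "/"), ")\n", sep = "")
  invisible(x)
}

#' @rdname home_range_ud
#' @param x A `frog_ud` object.
#' @param ... Unused.
#' @export
tidy.frog_ud <- function(x, ...) {
  purrr::imap_dfr(x$contours, function(cl, i) {
    tibble::tibble(contour = i, x = cl$x, y = cl$y)
  })
}

#' @rdname home_range_ud
#' @export
glance.frog_ud <- function(x, ...) {
  tibble::tibble(area_m2 = x$area_m2, ud_level = x$ud_level,
                 hx = x$h[["hx"]], hy = x$h[["hy"]], n = x$n)
}

#' Convert UD contours or an MCP to polygons
#'
#' @param x A `frog_ud` or `frog_mcp` object.
#' @return A list of [geo_polygon()] objects (one per contour ring).
#' @export
as_geo_polygons <- function(x) {
  if (inherits(x, "frog_mcp")) {
    return(list(geo_polygon(x$vertices, name = "mcp")))
  }
  if (inherits(x, "frog_ud")) {
    return(purrr::imap(x$contours, function(cl, i) {
      geo_polygon(cbind(cl$x, cl$y), name = paste0("ud_", i))
    }))
  }
  abort("as_geo_polygons() handles frog_mcp and frog_ud objects")
}

#' Signed percent difference between two group means
#'
#' `100 * (a - b) / b` on the natural (back-transformed) scale: the
#' reporting convention for statements such as "male home range was 153%
#' larger than female".
#'
#' @param a,b Positive group means; `b` is the reference group.
#' @return Signed percent.
#' @export
percent_difference <- function(a, b) {
  if (any(b <= 0)) abort("reference mean must be positive")
  100 * (a - b) / b
}

#' Per-animal space-use summary
#'
#' Computes, per animal: mean daily travel, MCP movement-extent area,
#' maximum linear extent, kernel home range, and days tracked. The kernel
#' home range is reported only for animals tracked at least `min_days_hr`
#' days with at least 8 fixes (short tracks cannot support a UD estimate);
#' others get `NA`.
#'
#' @param fixes Fix tibble (typically already downsampled with
#'   [downsample_two_step()]).
#' @param cfg A [kde_config()].
#' @param min_days_hr Minimum days tracked for home-range estimation
#'   (default 7).
#' @return A tibble with one row per animal: `animal_id`, `days_tracked`,
#'   `n_fixes`, `daily_travel_mean_m`, `extent_area_m2`,
#'   `extent_distance_m`, `home_range_m2`.
#' @export
space_use_summary <- function(fixes, cfg = kde_config(), min_days_hr = 7) {
  fixes <- as_fixes(fixes)
  fixes$..date <- local_date(fixes$t)
  fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(tr, key) {
      travel <- tr |>
        dplyr::group_by(.data$..date) |>
        dplyr::summarise(d = path_length(.data$x, .data$y),
                         .groups = "drop")
      days <- length(unique(tr$..date))
      hr <- if (days >= min_days_hr && nrow(tr) >= 8 &&
                stats::sd(tr$x) > 0 && stats::sd(tr$y) > 0) {
        home_range_ud(tr, cfg)$area_m2
      } else {
        NA_real_
      }
      tibble::tibble(
        days_tracked = days,
        n_fixes = nrow(tr),
        daily_travel_mean_m = mean(travel$d),
        extent_area_m2 = mcp_extent(tr)$area_m2,
        extent_distance_m = extent_distance(tr),
        home_range_m2 = hr
      )
    }) |>
    dplyr::ungroup()
}
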