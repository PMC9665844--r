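# Independent oracles and fixture builders. Everything here is deliberately
# naive (brute force / closed form) and shares no code with the package
# internals it checks.

# quick fix-table constructor: evenly spaced times on one or more days
fix_tbl <- function(x, y, id = "a", start = "2026-01-01 08:00:00",
                    by_min = 60, t = NULL, behavior = NULL, ...) {
  n <- length(x)
  if (is.null(t)) {
    t <- as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * by_min * 60
  }
  out <- tibble::tibble(animal_id = id, t = t, x = x, y = y, ...)
  if (!is.null(behavior)) out$behavior <- behavior
  out
}

oracle_shoelace <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# O(n^3) convex hull area: an ordered pair (i, j) is a hull edge iff every
# other point lies on or to one side of it; hull vertices are the edge
# endpoints, ordered by angle around their centroid
oracle_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n < 3) return(0)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      others <- setdiff(seq_len(n), c(i, j))
      cr <- (pts[j, 1] - pts[i, 1]) * (pts[others, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[others, 1] - pts[i, 1])
      if (all(cr <= 1e-12)) {
        on_hull[c(i, j)] <- TRUE
      }
    }
  }
  hx <- pts[on_hull, 1]
  hy <- pts[on_hull, 2]
  o <- order(atan2(hy - mean(hy), hx - mean(hx)))
  oracle_shoelace(hx[o], hy[o])
}

# O(n^2) maximum pairwise distance
oracle_max_dist <- function(x, y) {
  n <- length(x)
  d <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- max(d, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
    }
  }
  d
}

# home area whose centre is exactly (cx, cy): symmetric square of fixes
square_home <- function(cx, cy, half = 1, id = "a") {
  home_area(fix_tbl(x = cx + c(-1, 1, 1, -1) * half,
                    y = cy + c(-1, -1, 1, 1) * half,
                    id = id, start = "2026-01-01 08:00:00"))
}

# hand-built translocation record
mk_record <- function(track_x, track_y, release = c(0, 0),
                      home = square_home(50, 0),
                      release_time = as.POSIXct("2026-01-02 12:00:00",
                                                tz = "UTC"),
                      t = NULL, distance_class = "d50", id = "a") {
  if (is.null(t)) {
    t <- release_time + seq_along(track_x) * 900
  }
  translocation_record(
    id, release, release_time, distance_class, home,
    fix_tbl(track_x, track_y, id = id, t = t)
  )
}

# beeline homing parameters: deterministic straight walk home
beeline_params <- function(distance_class = "d50", step = 4) {
  homing_params(
    distance_class = distance_class,
    p_state = matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE,
                     dimnames = list(c("local", "explore", "home"),
                                     c("local", "explore", "home"))),
    kappa_home = Inf, step_mean_m = step, start_state = "home"
  )
}

# stationary parameters: never leaves the release site
stay_params <- function(distance_class = "d50") {
  homing_params(
    distance_class = distance_class,
    p_state = matrix(c(1, 0, 0, 1, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE,
                     dimnames = list(c("local", "explore", "home"),
                                     c("local", "explore", "home"))),
    start_state = "local"
  )
}
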