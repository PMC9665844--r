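# Internal geometry and time helpers. All coordinates are planar metres in a
# local engineering frame; no geodesy anywhere in the package.

# wrap an angle into (-pi, pi]
wrap_pi <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# mathematical bearing of the vector from -> to (radians CCW from +x axis)
bearing <- function(from, to) {
  atan2(to[2] - from[2], to[1] - from[1])
}

dist2d <- function(p, q) sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)

# cumulative path length over ordered coordinates
path_length <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# max pairwise Euclidean distance, O(n^2); used on hull vertices
max_pairwise_dist <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  d <- 0
  for (i in seq_len(n - 1)) {
    di <- sqrt((x[(i + 1):n] - x[i])^2 + (y[(i + 1):n] - y[i])^2)
    d <- max(d, di)
  }
  d
}

# shoelace area of a polygon given by vertices in order (not repeated)
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# distance from points (px, py) to segments (ax, ay)-(bx, by); vectorised in
# both the points and the segments (usual recycling rules)
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  # degenerate segments (a == b) are safe: s clamps and b - a is zero
  s <- ((px - ax) * dx + (py - ay) * dy) / pmax(len2, .Machine$double.xmin)
  s <- pmin(1, pmax(0, s))
  sqrt((px - (ax + s * dx))^2 + (py - (ay + s * dy))^2)
}

# is point p inside (or on) the convex polygon with vertices vx, vy (in order)?
point_in_convex <- function(p, vx, vy) {
  n <- length(vx)
  if (n == 1) return(p[1] == vx && p[2] == vy)
  if (n == 2) {
    return(point_segment_dist(p[1], p[2], vx[1], vy[1], vx[2], vy[2]) < 1e-12)
  }
  j <- c(seq(2, n), 1)
  cr <- (vx[j] - vx) * (p[2] - vy) - (vy[j] - vy) * (p[1] - vx)
  all(cr >= -1e-9) || all(cr <= 1e-9)
}

# distance from point p to a convex polygon (0 if inside)
dist_to_convex <- function(p, vx, vy) {
  n <- length(vx)
  if (n == 1) return(dist2d(p, c(vx, vy)))
  if (point_in_convex(p, vx, vy)) return(0)
  j <- c(seq(2, n), 1)
  min(point_segment_dist(p[1], p[2], vx, vy, vx[j], vy[j]))
}

# convex hull vertices (counter-clockwise), as a two-column matrix
hull_vertices <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) <= 2) {
    return(pts)
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[rev(idx), , drop = FALSE] # chull is clockwise; reverse to CCW
}

local_date <- function(t) as.Date(t, tz = "UTC")

hour_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

# overlap in hours of the interval [t0, t1] with daytime windows
# [day_start, day_end) (hours of day) on every calendar day it spans
daytime_overlap_hours <- function(t0, t1, day_start = 6, day_end = 18) {
  if (t1 <= t0) return(0)
  total <- 0
  dates <- seq(local_date(t0), local_date(t1), by = "day")
  for (d in as.list(dates)) {
    d0 <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
    w0 <- d0 + day_start * 3600
    w1 <- d0 + day_end * 3600
    lo <- max(as.numeric(t0), as.numeric(w0))
    hi <- min(as.numeric(t1), as.numeric(w1))
    if (hi > lo) total <- total + (hi - lo) / 3600
  }
  total
}
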