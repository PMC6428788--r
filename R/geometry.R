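# Low-level 2-D polyline geometry shared by the contour, mesh and
# evaluation code. All coordinates are millimetres in patient space;
# in-slice angles are measured counter-clockwise from the +x axis.

#' @keywords internal
wrap_angle <- function(a) {
  # wrap to (-180, 180]
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

#' @keywords internal
deg2rad <- function(d) d * pi / 180

#' @keywords internal
rad2deg <- function(r) r * 180 / pi

# Close a polyline: ensure first point is not repeated at the end.
#' @keywords internal
strip_closure <- function(p) {
  if (nrow(p) > 1 && all(abs(p[1, ] - p[nrow(p), ]) < 1e-12)) p[-nrow(p), , drop = FALSE] else p
}

# Segment representation of an implicitly closed polyline: rows i -> i+1,
# last row wraps to the first point.
#' @keywords internal
polyline_segments <- function(p) {
  p2 <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  list(a = p, b = p2, len = sqrt(rowSums((p2 - p)^2)))
}

#' @keywords internal
polyline_perimeter <- function(p) sum(polyline_segments(strip_closure(p))$len)

#' @keywords internal
polygon_centroid <- function(p) {
  p <- strip_closure(p)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) return(colMeans(p))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' @keywords internal
polygon_signed_area <- function(p) {
  p <- strip_closure(p)
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# Even-odd point-in-polygon test (delegates to mgcv's implementation).
#' @keywords internal
points_in_polygon <- function(poly, pts) {
  poly <- strip_closure(poly)
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, matrix(pts, ncol = 2))
}

# Does any pair of non-adjacent segments of the closed polyline intersect?
#' @keywords internal
polyline_self_intersects <- function(p) {
  p <- strip_closure(p)
  n <- nrow(p)
  if (n < 4) return(FALSE)
  s <- polyline_segments(p)
  for (i in seq_len(n - 2)) {
    # skip the two adjacent segments (and the wrap pair for i = 1)
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    if (!length(js)) next
    if (any(segments_cross(s$a[i, ], s$b[i, ], s$a[js, , drop = FALSE], s$b[js, , drop = FALSE])))
      return(TRUE)
  }
  FALSE
}

# Vectorized proper-crossing test of segment (p1,p2) against segments (a,b).
#' @keywords internal
segments_cross <- function(p1, p2, a, b) {
  v <- p2 - p1
  d1 <- v[1] * (a[, 2] - p1[2]) - v[2] * (a[, 1] - p1[1])
  d2 <- v[1] * (b[, 2] - p1[2]) - v[2] * (b[, 1] - p1[1])
  d3 <- (b[, 1] - a[, 1]) * (p1[2] - a[, 2]) - (b[, 2] - a[, 2]) * (p1[1] - a[, 1])
  d4 <- (b[, 1] - a[, 1]) * (p2[2] - a[, 2]) - (b[, 2] - a[, 2]) * (p2[1] - a[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# First intersection of the ray origin + t*dir (t > eps) with a closed
# polyline; returns list(point, t) or NULL when the ray misses.
#' @keywords internal
ray_polyline_intersection <- function(origin, dir, poly, eps = 1e-9) {
  poly <- strip_closure(poly)
  s <- polyline_segments(poly)
  e <- s$b - s$a
  # solve origin + t*dir = a + u*e, 0 <= u < 1, t > eps
  denom <- dir[1] * e[, 2] - dir[2] * e[, 1]
  ok <- abs(denom) > 1e-14
  ao <- t(t(s$a) - origin)
  tt <- (ao[, 1] * e[, 2] - ao[, 2] * e[, 1]) / denom
  uu <- (ao[, 1] * dir[2] - ao[, 2] * dir[1]) / -denom
  hit <- ok & tt > eps & uu >= -1e-12 & uu <= 1 + 1e-12
  if (!any(hit)) return(NULL)
  tbest <- min(tt[hit])
  list(point = origin + tbest * dir, t = tbest)
}

# Closest point on a closed polyline to point q: returns the point, its
# arc-length position s (measured from vertex 1 along the polyline) and
# the distance.
#' @keywords internal
closest_point_on_polyline <- function(poly, q) {
  poly <- strip_closure(poly)
  s <- polyline_segments(poly)
  e <- s$b - s$a
  len2 <- pmax(rowSums(e^2), 1e-300)
  aq <- t(t(-s$a) + q)
  u <- pmin(pmax((aq[, 1] * e[, 1] + aq[, 2] * e[, 2]) / len2, 0), 1)
  px <- s$a[, 1] + u * e[, 1]
  py <- s$a[, 2] + u * e[, 2]
  d2 <- (px - q[1])^2 + (py - q[2])^2
  i <- which.min(d2)
  cum <- c(0, cumsum(s$len))
  list(point = c(px[i], py[i]),
       s = cum[i] + u[i] * s$len[i],
       dist = sqrt(d2[i]),
       segment = i)
}

# Resample an implicitly closed polyline to n points equally spaced in arc
# length, starting at the crossing of the ray from `center` at angle
# `start_angle_deg` (default 0). Points stay on the original polyline.
#' @keywords internal
resample_closed_polyline <- function(poly, n, center = NULL, start_angle_deg = 0) {
  poly <- strip_closure(poly)
  if (is.null(center)) center <- polygon_centroid(poly)
  dir <- c(cos(deg2rad(start_angle_deg)), sin(deg2rad(start_angle_deg)))
  hit <- ray_polyline_intersection(center, dir, poly)
  if (is.null(hit)) stop("start ray does not intersect the contour")
  start <- hit$point
  # arc position of the start point
  s0 <- closest_point_on_polyline(poly, start)$s
  seg <- polyline_segments(poly)
  L <- sum(seg$len)
  cum <- c(0, cumsum(seg$len))
  svals <- (s0 + (0:(n - 1)) / n * L) %% L
  idx <- findInterval(svals, cum, rightmost.closed = TRUE)
  idx[idx > nrow(poly)] <- nrow(poly)
  u <- (svals - cum[idx]) / pmax(seg$len[idx], 1e-300)
  cbind(seg$a[idx, 1] + u * (seg$b[idx, 1] - seg$a[idx, 1]),
        seg$a[idx, 2] + u * (seg$b[idx, 2] - seg$a[idx, 2]))
}
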