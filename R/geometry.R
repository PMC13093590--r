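# Internal planar geometry helpers. All coordinates are meters in a projected
# CRS; polylines are n x 2 matrices of vertices.

polyline_length <- function(coords) {
  if (nrow(coords) < 2) return(0)
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

# cumulative arc length at each vertex (first = 0)
polyline_measures <- function(coords) {
  if (nrow(coords) < 2) return(0)
  c(0, cumsum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)))
}

# point (and unit tangent) at arc-length `measure` along a polyline; measure
# is clamped to [0, length]
point_along_polyline <- function(coords, measure) {
  mv <- polyline_measures(coords)
  len <- mv[length(mv)]
  m <- min(max(measure, 0), len)
  seg <- findInterval(m, mv, rightmost.closed = TRUE)
  seg <- min(max(seg, 1L), nrow(coords) - 1L)
  a <- coords[seg, ]
  b <- coords[seg + 1L, ]
  seg_len <- sqrt(sum((b - a)^2))
  t <- if (seg_len > 0) (m - mv[seg]) / seg_len else 0
  tangent <- if (seg_len > 0) (b - a) / seg_len else c(1, 0)
  list(xy = a + t * (b - a), tangent = tangent, segment = seg)
}

# perpendicular projection of point p onto a polyline: returns the measure,
# offset distance, and foot coordinates of the nearest point
project_point_polyline <- function(coords, p) {
  ax <- coords[-nrow(coords), 1]; ay <- coords[-nrow(coords), 2]
  bx <- coords[-1, 1];            by <- coords[-1, 2]
  dx <- bx - ax; dy <- by - ay
  seg2 <- dx^2 + dy^2
  t <- ifelse(seg2 > 0, ((p[1] - ax) * dx + (p[2] - ay) * dy) / seg2, 0)
  t <- pmin(pmax(t, 0), 1)
  fx <- ax + t * dx; fy <- ay + t * dy
  d2 <- (p[1] - fx)^2 + (p[2] - fy)^2
  i <- which.min(d2)
  mv <- polyline_measures(coords)
  list(measure = mv[i] + t[i] * sqrt(seg2[i]),
       offset = sqrt(d2[i]),
       xy = c(fx[i], fy[i]))
}

# minimum distance from point p to a polyline
dist_point_polyline <- function(coords, p) {
  if (nrow(coords) == 1) return(sqrt(sum((p - coords[1, ])^2)))
  project_point_polyline(coords, p)$offset
}

seg_intersects <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, a, b) {
    min(a[1], b[1]) - 1e-12 <= p[1] && p[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= p[2] && p[2] <= max(a[2], b[2]) + 1e-12
  }
  (d1 == 0 && on_seg(p1, p3, p4)) || (d2 == 0 && on_seg(p2, p3, p4)) ||
  (d3 == 0 && on_seg(p3, p1, p2)) || (d4 == 0 && on_seg(p4, p1, p2))
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

dist_point_segment <- function(p, a, b) {
  d <- b - a
  seg2 <- sum(d^2)
  t <- if (seg2 > 0) sum((p - a) * d) / seg2 else 0
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * d))^2))
}

dist_seg_seg <- function(p1, p2, p3, p4) {
  if (seg_intersects(p1, p2, p3, p4)) return(0)
  min(dist_point_segment(p1, p3, p4), dist_point_segment(p2, p3, p4),
      dist_point_segment(p3, p1, p2), dist_point_segment(p4, p1, p2))
}

# minimum distance between two polylines (0 if they cross)
dist_polyline_polyline <- function(a, b) {
  if (nrow(a) == 1 && nrow(b) == 1) return(sqrt(sum((a[1, ] - b[1, ])^2)))
  if (nrow(a) == 1) return(dist_point_polyline(b, a[1, ]))
  if (nrow(b) == 1) return(dist_point_polyline(a, b[1, ]))
  best <- Inf
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      d <- dist_seg_seg(a[i, ], a[i + 1, ], b[j, ], b[j + 1, ])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

# ---- vectorized segment distances (used on large LCP segment sets) ----

# flatten a list of polylines into one segment matrix (x1, y1, x2, y2)
segments_from_paths <- function(paths) {
  segs <- purrr::map(paths, function(m) {
    if (is.null(m) || nrow(m) < 2) return(NULL)
    cbind(m[-nrow(m), 1], m[-nrow(m), 2], m[-1, 1], m[-1, 2])
  })
  out <- do.call(rbind, purrr::compact(segs))
  if (is.null(out)) matrix(numeric(0), ncol = 4) else out
}

# distance from one point to many segments
dist_point_segments <- function(p, segs) {
  dx <- segs[, 3] - segs[, 1]; dy <- segs[, 4] - segs[, 2]
  seg2 <- dx^2 + dy^2
  t <- ifelse(seg2 > 0,
              ((p[1] - segs[, 1]) * dx + (p[2] - segs[, 2]) * dy) / seg2, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt((p[1] - (segs[, 1] + t * dx))^2 + (p[2] - (segs[, 2] + t * dy))^2)
}

# distance from many points to one segment (a, b)
dist_points_segment <- function(px, py, a, b) {
  d <- b - a
  seg2 <- sum(d^2)
  t <- if (seg2 > 0) ((px - a[1]) * d[1] + (py - a[2]) * d[2]) / seg2 else 0
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (a[1] + t * d[1]))^2 + (py - (a[2] + t * d[2]))^2)
}

# exact minimum distance from one segment (a1, a2) to many segments
dist_segment_segments <- function(a1, a2, segs) {
  if (nrow(segs) == 0) return(numeric(0))
  # orientation tests for proper intersection, vectorized over segs
  o <- function(px, py, qx, qy, rx, ry) {
    (qx - px) * (ry - py) - (qy - py) * (rx - px)
  }
  d1 <- o(segs[, 1], segs[, 2], segs[, 3], segs[, 4], a1[1], a1[2])
  d2 <- o(segs[, 1], segs[, 2], segs[, 3], segs[, 4], a2[1], a2[2])
  d3 <- o(a1[1], a1[2], a2[1], a2[2], segs[, 1], segs[, 2])
  d4 <- o(a1[1], a1[2], a2[1], a2[2], segs[, 3], segs[, 4])
  inter <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
           ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  dmin <- pmin(
    dist_point_segments(a1, segs),
    dist_point_segments(a2, segs),
    dist_points_segment(segs[, 1], segs[, 2], a1, a2),
    dist_points_segment(segs[, 3], segs[, 4], a1, a2)
  )
  # collinear touching cases are caught by dmin == 0 via the point distances
  dmin[inter] <- 0
  dmin
}

# minimum distance from a polyline (or single point matrix) to a segment set
dist_polyline_segments <- function(poly, segs) {
  if (nrow(segs) == 0) return(Inf)
  if (nrow(poly) == 1) return(min(dist_point_segments(poly[1, ], segs)))
  best <- Inf
  for (i in seq_len(nrow(poly) - 1)) {
    best <- min(best, dist_segment_segments(poly[i, ], poly[i + 1, ], segs))
    if (best == 0) break
  }
  best
}
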