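# Planar geometry primitives. All coordinates are metres in the projected
# study frame; polygons are n x 2 matrices of vertices (closed implicitly,
# last vertex need not repeat the first).

.close_ring <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n > 1 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  poly
}

#' Point-in-polygon test
#'
#' Even-odd (ray casting) containment test, vectorised over points. Points
#' lying on the polygon boundary (within `tol` metres) count as inside by
#' default, matching the interaction rule that boundary contact is contact.
#'
#' @param px,py Numeric vectors of point coordinates (m).
#' @param poly An n x 2 matrix of polygon vertices.
#' @param boundary_in Treat points on the boundary as inside?
#' @param tol Boundary snap tolerance in metres.
#' @return Logical vector, one element per point.
#' @export
point_in_polygon <- function(px, py, poly, boundary_in = TRUE, tol = 1e-9) {
  poly <- .close_ring(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  nv <- length(xs)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2
      onedge <- onedge | d2 <= tol * tol
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  if (boundary_in) inside | onedge else inside & !onedge
}

# Signed twice-area of triangle abc; sign gives orientation.
.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_segment <- function(ax, ay, bx, by, px, py, tol = 1e-12) {
  px >= pmin(ax, bx) - tol & px <= pmax(ax, bx) + tol &
    py >= pmin(ay, by) - tol & py <= pmax(ay, by) + tol
}

#' Segment-segment intersection test
#'
#' Closed test: touching at an endpoint or collinear overlap counts as
#' intersecting. Vectorised over the first segment set.
#'
#' @param ax,ay,bx,by Endpoints of the first segment(s) (vectors).
#' @param cx,cy,dx,dy Endpoints of the second segment (scalars).
#' @return Logical vector.
#' @export
segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- .orient(cx, cy, dx, dy, ax, ay)
  d2 <- .orient(cx, cy, dx, dy, bx, by)
  d3 <- .orient(ax, ay, bx, by, cx, cy)
  d4 <- .orient(ax, ay, bx, by, dx, dy)
  proper <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  touch <- (d1 == 0 & .on_segment(cx, cy, dx, dy, ax, ay)) |
    (d2 == 0 & .on_segment(cx, cy, dx, dy, bx, by)) |
    (d3 == 0 & .on_segment(ax, ay, bx, by, cx, cy)) |
    (d4 == 0 & .on_segment(ax, ay, bx, by, dx, dy))
  proper | touch
}

# Strictly crossing interiors (no shared endpoints, no collinear touch);
# used for polygon self-intersection and overlap detection. `tol` is the
# minimum perpendicular penetration (m) for a crossing to count, so that
# abutting edges reconstructed through floating-point round-trips do not
# register as overlap.
.segments_cross_proper <- function(ax, ay, bx, by, cx, cy, dx, dy, tol = 0) {
  d1 <- .orient(cx, cy, dx, dy, ax, ay)
  d2 <- .orient(cx, cy, dx, dy, bx, by)
  d3 <- .orient(ax, ay, bx, by, cx, cy)
  d4 <- .orient(ax, ay, bx, by, dx, dy)
  lcd <- sqrt((dx - cx)^2 + (dy - cy)^2)
  lab <- sqrt((bx - ax)^2 + (by - ay)^2)
  e12 <- tol * lcd
  e34 <- tol * lab
  ((d1 > e12 & d2 < -e12) | (d1 < -e12 & d2 > e12)) &
    ((d3 > e34 & d4 < -e34) | (d3 < -e34 & d4 > e34))
}

#' Does a segment intersect a polygon?
#'
#' TRUE when the closed segment meets the closed polygon region: either
#' endpoint inside (boundary included) or the segment crosses/touches any
#' polygon edge. Vectorised over segments.
#'
#' @param ax,ay,bx,by Segment endpoint vectors (m).
#' @param poly An n x 2 vertex matrix.
#' @return Logical vector, one element per segment.
#' @export
segment_intersects_polygon <- function(ax, ay, bx, by, poly) {
  poly <- .close_ring(poly)
  hit <- point_in_polygon(ax, ay, poly) | point_in_polygon(bx, by, poly)
  if (all(hit)) return(hit)
  xs <- poly[, 1]; ys <- poly[, 2]
  nv <- length(xs)
  j <- nv
  for (i in seq_len(nv)) {
    todo <- !hit
    if (!any(todo)) break
    hit[todo] <- segments_intersect(ax[todo], ay[todo], bx[todo], by[todo],
                                    xs[j], ys[j], xs[i], ys[i])
    j <- i
  }
  hit
}

#' Polygon area (shoelace)
#'
#' @param poly An n x 2 vertex matrix.
#' @param signed Return the signed area (positive for counter-clockwise)?
#' @return Area in square metres.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  poly <- .close_ring(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- sum(x * yn - xn * y) / 2
  if (signed) a else abs(a)
}

# TRUE if any two non-adjacent edges of the ring cross properly (bow-tie).
.polygon_self_intersects <- function(poly) {
  poly <- .close_ring(poly)
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the wrap
      a <- poly[idx[i, 1], ]; b <- poly[idx[i, 2], ]
      c_ <- poly[idx[j, 1], ]; d <- poly[idx[j, 2], ]
      if (.segments_cross_proper(a[1], a[2], b[1], b[2],
                                 c_[1], c_[2], d[1], d[2])) return(TRUE)
    }
  }
  FALSE
}

# Positive-area overlap between two simple polygons. Shared edges/vertices
# (abutting surfaces) do not count; proper edge crossing or strict
# containment of an interior point does. `tol` (m) absorbs floating-point
# jitter from coordinate round-trips.
.polygons_overlap <- function(p1, p2, tol = 1e-3) {
  p1 <- .close_ring(p1); p2 <- .close_ring(p2)
  n1 <- nrow(p1); n2 <- nrow(p2)
  e1 <- cbind(seq_len(n1), c(seq_len(n1)[-1], 1))
  e2 <- cbind(seq_len(n2), c(seq_len(n2)[-1], 1))
  for (i in seq_len(n1)) {
    a <- p1[e1[i, 1], ]; b <- p1[e1[i, 2], ]
    for (j in seq_len(n2)) {
      c_ <- p2[e2[j, 1], ]; d <- p2[e2[j, 2], ]
      if (.segments_cross_proper(a[1], a[2], b[1], b[2],
                                 c_[1], c_[2], d[1], d[2], tol = tol)) {
        return(TRUE)
      }
    }
  }
  # containment without edge crossing: test an interior sample of each ring
  c1 <- colMeans(p1); c2 <- colMeans(p2)
  if (point_in_polygon(c1[1], c1[2], p1, boundary_in = FALSE, tol = tol) &&
      point_in_polygon(c1[1], c1[2], p2, boundary_in = FALSE, tol = tol)) return(TRUE)
  if (point_in_polygon(c2[1], c2[2], p2, boundary_in = FALSE, tol = tol) &&
      point_in_polygon(c2[1], c2[2], p1, boundary_in = FALSE, tol = tol)) return(TRUE)
  any(point_in_polygon(p1[, 1], p1[, 2], p2, boundary_in = FALSE, tol = tol)) ||
    any(point_in_polygon(p2[, 1], p2[, 2], p1, boundary_in = FALSE, tol = tol))
}
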