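# Planar geometry for region polygons.  All coordinates are micrometres.
# Polygons are numeric matrices with two columns (x, y), one row per vertex,
# stored as open rings (the closing vertex is implied, not repeated).

#' Area of a simple polygon
#'
#' Shoelace (surveyor's) formula.  The ring may be given open or closed
#' (first vertex repeated at the end); orientation does not matter.
#'
#' @param poly numeric matrix with columns x, y (micrometres).
#' @return area in square micrometres.
#' @export
polygon_area <- function(poly) {
  poly <- normalize_ring(poly)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Drop a repeated closing vertex and validate vertex count.
normalize_ring <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2) stop("polygon must have two coordinate columns")
  if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  if (nrow(unique(poly)) < 3) {
    stop("degenerate ring: fewer than 3 distinct vertices")
  }
  storage.mode(poly) <- "double"
  unname(poly)
}

# Counter-clockwise orientation (positive signed area).
ensure_ccw <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  if (sum(x * y[j] - x[j] * y) < 0) poly[n:1, , drop = FALSE] else poly
}

is_convex_ring <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1); k <- c(3:n, 1, 2)
  cr <- (poly[j, 1] - poly[, 1]) * (poly[k, 2] - poly[j, 2]) -
        (poly[j, 2] - poly[, 2]) * (poly[k, 1] - poly[j, 1])
  all(cr >= -1e-9 * max(abs(cr), 1)) || all(cr <= 1e-9 * max(abs(cr), 1))
}

# Proper self-intersection test between non-adjacent edges (O(n^2); rings are
# small).  Touching at shared endpoints of adjacent edges is allowed.
is_simple_ring <- function(poly) {
  n <- nrow(poly)
  a1 <- poly; a2 <- poly[c(2:n, 1), , drop = FALSE]
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
    d2 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
    d3 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next   # adjacent through the closing edge
      if (seg_int(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Point-in-polygon test
#'
#' Even-odd (crossing number) rule with a closed boundary: points lying on a
#' polygon edge count as inside.
#'
#' @param px,py point coordinates (micrometres).
#' @param poly polygon matrix.
#' @param tol absolute distance (micrometres) within which a point is treated
#'   as on the boundary.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, poly, tol = 1e-9) {
  poly <- normalize_ring(poly)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- poly[c(2:n, 1), 1]; ye <- poly[c(2:n, 1), 2]
  inside <- logical(length(px))
  onb <- logical(length(px))
  for (i in seq_len(n)) {
    ax <- xs[i]; ay <- ys[i]; bx <- xe[i]; by <- ye[i]
    dx <- bx - ax; dy <- by - ay
    l2 <- dx * dx + dy * dy
    tt <- if (l2 > 0) pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2)) else 0
    d2 <- (px - (ax + tt * dx))^2 + (py - (ay + tt * dy))^2
    onb <- onb | d2 <= tol * tol
    crosses <- ((ay > py) != (by > py))
    if (any(crosses)) {
      xint <- ax + (py - ay) * dx / dy  # dy != 0 where crosses
      hit <- crosses & (px < xint)
      inside <- xor(inside, hit)
    }
  }
  inside | onb
}

# Regular k-gon approximation of a disc (counter-clockwise).
disc_polygon <- function(cx, cy, r, k = 128L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Convex hull of a point set, counter-clockwise ring.
convex_hull <- function(x, y) {
  idx <- grDevices::chull(x, y)      # clockwise order
  ensure_ccw(cbind(x[idx], y[idx]))
}

# Minkowski dilation of a point set by a disc of radius r, approximated by a
# k-gon per point, then the convex hull.  Handles collinear/degenerate sets
# (the result is a capsule).  r = 0 returns the plain hull.
buffered_hull <- function(x, y, r, k = 32L) {
  if (r > 0) {
    th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
    x <- as.vector(outer(x, r * cos(th), "+"))
    y <- as.vector(outer(y, r * sin(th), "+"))
  }
  convex_hull(x, y)
}

# Sutherland-Hodgman clipping of a polygon against a convex clip ring.
# Returns NULL when the intersection is empty/degenerate.
clip_to_convex <- function(subject, clip) {
  clip <- ensure_ccw(normalize_ring(clip))
  out <- normalize_ring(subject)
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == n) 1 else i + 1, ]
    m <- nrow(out)
    side <- (b[1] - a[1]) * (out[, 2] - a[2]) - (b[2] - a[2]) * (out[, 1] - a[1]) >= 0
    res <- vector("list", 2L * m)
    nk <- 0L
    for (kk in seq_len(m)) {
      kp <- if (kk == 1) m else kk - 1
      if (side[kk]) {
        if (!side[kp]) {
          nk <- nk + 1L
          res[[nk]] <- line_intersection(out[kp, ], out[kk, ], a, b)
        }
        nk <- nk + 1L
        res[[nk]] <- out[kk, ]
      } else if (side[kp]) {
        nk <- nk + 1L
        res[[nk]] <- line_intersection(out[kp, ], out[kk, ], a, b)
      }
    }
    out <- if (nk) do.call(rbind, res[seq_len(nk)]) else NULL
  }
  if (is.null(out) || nrow(out) < 3) return(NULL)
  out
}

# Intersection of segment p->q with the infinite line through a->b.
line_intersection <- function(p, q, a, b) {
  den <- (q[1] - p[1]) * (b[2] - a[2]) - (q[2] - p[2]) * (b[1] - a[1])
  if (abs(den) < .Machine$double.eps) return(p)
  t <- ((a[1] - p[1]) * (b[2] - a[2]) - (a[2] - p[2]) * (b[1] - a[1])) / den
  p + t * (q - p)
}

# Area (um^2) of the union of a list of rings, each clipped to a convex
# window ring first.  Exact inclusion-exclusion via convex clipping when all
# rings are convex; otherwise a deterministic fine-grid approximation.
union_area <- function(polys, window_ring = NULL) {
  polys <- Filter(Negate(is.null), polys)
  if (!is.null(window_ring)) {
    polys <- lapply(polys, clip_to_convex, clip = window_ring)
    polys <- Filter(Negate(is.null), polys)
  }
  if (length(polys) == 0) return(0)
  polys <- lapply(polys, function(p) ensure_ccw(normalize_ring(p)))
  if (all(vapply(polys, is_convex_ring, logical(1)))) {
    return(union_area_convex(polys))
  }
  union_area_grid(polys)
}

union_area_convex <- function(polys) {
  n <- length(polys)
  bbs <- lapply(polys, function(p) c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2])))
  total <- 0
  recurse <- function(start, inter, bb, depth) {
    for (i in start:n) {
      bbi <- bbs[[i]]
      if (!is.null(bb) &&
          (bbi[1] > bb[3] || bbi[3] < bb[1] || bbi[2] > bb[4] || bbi[4] < bb[2])) next
      cur <- if (is.null(inter)) polys[[i]] else clip_to_convex(inter, polys[[i]])
      if (is.null(cur)) next
      a <- polygon_area(cur)
      if (a <= 0) next
      total <<- total + if (depth %% 2 == 1) a else -a
      if (i < n) {
        bbc <- c(min(cur[, 1]), min(cur[, 2]), max(cur[, 1]), max(cur[, 2]))
        recurse(i + 1, cur, bbc, depth + 1)
      }
    }
  }
  recurse(1, NULL, NULL, 1)
  total
}

# Deterministic midpoint-grid union area for non-convex rings; resolution is
# chosen so the expected boundary error is well below 0.1% of the bbox.
union_area_grid <- function(polys, n_cells = 1200L) {
  xs <- range(unlist(lapply(polys, function(p) p[, 1])))
  ys <- range(unlist(lapply(polys, function(p) p[, 2])))
  if (diff(xs) <= 0 || diff(ys) <= 0) return(0)
  gx <- seq(xs[1], xs[2], length.out = n_cells + 1L)
  gy <- seq(ys[1], ys[2], length.out = n_cells + 1L)
  cx <- (gx[-1] + gx[-length(gx)]) / 2
  cy <- (gy[-1] + gy[-length(gy)]) / 2
  pts <- expand.grid(x = cx, y = cy)
  covered <- logical(nrow(pts))
  for (p in polys) {
    todo <- which(!covered)
    if (!length(todo)) break
    covered[todo] <- points_in_polygon(pts$x[todo], pts$y[todo], p, tol = 0)
  }
  mean(covered) * diff(xs) * diff(ys)
}

# Axis-aligned window as a ccw ring.  window = c(xmin, ymin, xmax, ymax).
window_ring <- function(window) {
  cbind(c(window[1], window[3], window[3], window[1]),
        c(window[2], window[2], window[4], window[4]))
}
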