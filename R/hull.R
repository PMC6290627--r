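# Convex hull by Graham scan, shoelace area, and convex polygon clipping.
# Graham scan is well suited here: per-frame hulls of at most ~10 player
# positions, recomputed for every frame of a match.

# signed twice-area of triangle (o, a, b): > 0 means counter-clockwise turn
cross_orient <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Convex hull of a point set (Graham scan)
#'
#' Pivot is the lowest-y (ties: lowest-x) point; remaining points are sorted
#' by polar angle about the pivot, collinear ties by distance. Points interior
#' to the hull, and collinear points in the middle of hull edges, are not
#' vertices. If all points are collinear the hull is degenerate: the two
#' extreme points, area 0, flagged via `degenerate`.
#'
#' @param points Two-column matrix (or data frame) of `(x, y)` positions in
#'   meters; at least 3 points.
#' @return A `hull_polygon`: list with counter-clockwise `vertices` (matrix),
#'   `area` (m^2, by the shoelace formula) and logical `degenerate`.
#' @examples
#' convex_hull(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(1, 1)))
#' @export
convex_hull <- function(points) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2 || any(!is.finite(pts)))
    abort_domain("points must be a numeric 2-column matrix of finite (x, y)")
  if (nrow(pts) < 3)
    abort_group_size("convex hull needs at least 3 points")
  pts <- unique(pts)
  x <- pts[, 1]; y <- pts[, 2]
  n <- length(x)
  if (n < 3) return(degenerate_hull(x, y))

  piv <- order(y, x)[1]
  rest <- setdiff(seq_len(n), piv)
  ang <- atan2(y[rest] - y[piv], x[rest] - x[piv])
  d2 <- (x[rest] - x[piv])^2 + (y[rest] - y[piv])^2
  rest <- rest[order(ang, d2)]
  ord <- c(piv, rest)

  stack <- integer(0)
  for (i in ord) {
    while (length(stack) >= 2) {
      m <- length(stack)
      cr <- cross_orient(x[stack[m - 1]], y[stack[m - 1]],
                         x[stack[m]], y[stack[m]], x[i], y[i])
      if (cr > 1e-12) break        # strict left turn keeps the vertex
      stack <- stack[-m]           # right turn or collinear: drop midpoint
    }
    stack <- c(stack, i)
  }
  if (length(stack) < 3) return(degenerate_hull(x, y))
  vx <- x[stack]; vy <- y[stack]
  structure(list(vertices = cbind(x = vx, y = vy),
                 area = shoelace_area(vx, vy),
                 degenerate = FALSE),
            class = "hull_polygon")
}

degenerate_hull <- function(x, y) {
  # all collinear (or coincident): keep the two extreme points, area 0
  i <- order(x, y)
  ends <- unique(c(i[1], i[length(i)]))
  structure(list(vertices = cbind(x = x[ends], y = y[ends]),
                 area = 0, degenerate = TRUE),
            class = "hull_polygon")
}

#' @export
print.hull_polygon <- function(x, ...) {
  cat(sprintf("<hull_polygon> %d vertices, area %.3f m^2%s\n",
              nrow(x$vertices), x$area,
              if (x$degenerate) " (degenerate: collinear points)" else ""))
  invisible(x)
}

# Sutherland-Hodgman: clip CCW convex polygon `subj` (2-col matrix) by the
# half-planes of CCW convex polygon `clip`. Returns the intersection area.
convex_intersection_area <- function(subj, clip) {
  poly <- subj
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(poly) == 0) return(0)
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    keep <- cross_orient(a[1], a[2], b[1], b[2], poly[, 1], poly[, 2]) >= -1e-12
    np <- nrow(poly)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(np)) {
      j <- if (i == np) 1 else i + 1
      if (keep[i]) out <- rbind(out, poly[i, ])
      if (keep[i] != keep[j]) {
        p <- poly[i, ]; q <- poly[j, ]
        dp <- cross_orient(a[1], a[2], b[1], b[2], p[1], p[2])
        dq <- cross_orient(a[1], a[2], b[1], b[2], q[1], q[2])
        t <- dp / (dp - dq)
        out <- rbind(out, p + t * (q - p))
      }
    }
    poly <- out
  }
  if (nrow(poly) < 3) return(0)
  shoelace_area(poly[, 1], poly[, 2])
}
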