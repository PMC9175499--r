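# Planar geometry on annotation rings: pixel coordinates, x right / y down,
# origin top-left, implicit ring closure (first vertex not repeated).

as_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2) {
    stop("invalid geometry: a ring must be a numeric matrix with two columns (x, y)",
         call. = FALSE)
  }
  # drop an explicitly repeated closing vertex
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) {
    stop("invalid geometry: a ring needs at least 3 vertices", call. = FALSE)
  }
  ring
}

#' Polygon ring area by the shoelace formula
#'
#' Area of a simple polygon given as an ordered vertex list, in squared input
#' units (pixels squared for slide annotations). The ring is closed implicitly;
#' the result is orientation-independent.
#'
#' @param ring Numeric matrix (or two-column object coercible to one) of
#'   vertices, one `(x, y)` row each, at least three rows.
#' @return Non-negative area in squared input units.
#' @examples
#' ring_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # 1
#' @export
ring_area <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1]
  y <- ring[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# TRUE if p lies on the closed segment a--b (within tol, used for the
# boundary-counts-as-inside rule).
on_segment <- function(p, a, b, tol = 1e-9) {
  cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  scale <- max(abs(c(a, b, p)), 1)
  if (abs(cross) > tol * scale) return(FALSE)
  p[1] >= min(a[1], b[1]) - tol && p[1] <= max(a[1], b[1]) + tol &&
    p[2] >= min(a[2], b[2]) - tol && p[2] <= max(a[2], b[2]) + tol
}

# Even-odd ray casting. Returns "inside", "outside" or "boundary".
point_ring_position <- function(point, ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  px <- point[1]
  py <- point[2]
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if (on_segment(point, c(xi, yi), c(xj, yj))) return("boundary")
    if ((yi > py) != (yj > py)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  if (inside) "inside" else "outside"
}

#' Point-in-region containment test
#'
#' Even-odd ray-casting test of a point against a tissue region (outer ring
#' minus holes). Points on the outer boundary, or on a hole boundary, count as
#' inside tissue; points strictly inside a hole do not.
#'
#' @param point Numeric length-2 vector `(x, y)` in pixel coordinates.
#' @param region A [tissue_region()].
#' @return Logical scalar.
#' @export
point_in_region <- function(point, region) {
  stopifnot(inherits(region, "tissue_region"))
  pos <- point_ring_position(point, region$outer_ring)
  if (pos == "outside") return(FALSE)
  if (pos == "boundary") return(TRUE)
  for (hole in region$holes) {
    hpos <- point_ring_position(point, hole)
    if (hpos == "inside") return(FALSE)  # boundary of a hole stays in-tissue
  }
  TRUE
}
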