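# Polygon geometry primitives: point-in-polygon (even-odd rule),
# simplicity checks, and rasterization onto regular grids.
# All grids follow one convention: 0-based continuous coordinates,
# origin top-left, y increasing downward, cell (row r, col c) center at
# (xmin + (c - 0.5) * dx, ymin + (r - 0.5) * dy) with 1-based r, c.

wm_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "wingmatch_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

#' Coerce a polygon argument to a numeric vertex matrix
#'
#' Accepts a two-column matrix or data frame of vertices (x, y). A closing
#' vertex duplicating the first one is dropped.
#'
#' @param poly Matrix or data frame with two columns (x, y).
#' @return Numeric matrix with columns x, y, not explicitly closed.
#' @keywords internal
as_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || !is.numeric(poly)) {
    wm_stop("wm_geometry_error", "polygon must be a numeric matrix with columns x, y")
  }
  if (anyNA(poly) || any(!is.finite(poly))) {
    wm_stop("wm_geometry_error", "polygon vertices must be finite")
  }
  n <- nrow(poly)
  if (n >= 2L && all(poly[1L, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  colnames(poly) <- c("x", "y")
  poly
}

#' Even-odd point-in-polygon test
#'
#' Vectorized crossing-number test: a point is inside when a horizontal ray
#' from it crosses the polygon boundary an odd number of times (even-odd
#' rule). Points exactly on a horizontal edge follow the half-open edge
#' convention, which resolves boundary ties deterministically.
#'
#' @param px,py Numeric vectors of point coordinates (equal length).
#' @param poly Polygon vertex matrix (see [as_polygon()]).
#' @return Logical vector, `TRUE` for points strictly inside by even-odd rule.
#' @export
points_in_polygon <- function(px, py, poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  if (n < 3L) return(inside)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}

# strict segment crossing (shared endpoints between adjacent edges excluded)
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Checks every pair of non-adjacent edges for a proper crossing. Degenerate
#' polygons (fewer than three distinct vertices) are treated as simple with
#' zero area.
#'
#' @param poly Polygon vertex matrix.
#' @return Logical scalar.
#' @export
polygon_is_simple <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  if (n < 4L) return(TRUE)
  idx <- rbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # skip adjacent edges (share a vertex), incl. wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (.segments_cross(
        poly[idx[1L, i], ], poly[idx[2L, i], ],
        poly[idx[1L, j], ], poly[idx[2L, j], ]
      )) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Signed polygon area (shoelace formula)
#'
#' @param poly Polygon vertex matrix.
#' @return Numeric scalar; positive for counter-clockwise vertex order in a
#'   y-up frame (sign flips under the image y-down convention).
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Rasterize a polygon onto a regular grid
#'
#' Marks grid cells whose center falls inside the polygon by the even-odd
#' rule. This is the single rasterization primitive behind outline masks,
#' band rendering, exclusion masking and area counting, so that every area
#' in the package is a cell count under one convention.
#'
#' @param poly Polygon vertex matrix in grid coordinates.
#' @param nrow,ncol Grid dimensions (rows x cols).
#' @param bounds Numeric length-4 vector (xmin, ymin, xmax, ymax) mapped onto
#'   the grid; defaults to `c(0, 0, ncol, nrow)`, i.e. one cell per unit
#'   (pixel) square.
#' @param check_simple Reject self-intersecting polygons (default `TRUE`).
#' @return Integer 0/1 matrix of dimension `nrow` x `ncol`; row 1 is the top
#'   of the frame.
#' @export
rasterize_polygon <- function(poly, nrow, ncol, bounds = c(0, 0, ncol, nrow),
                              check_simple = TRUE) {
  poly <- as_polygon(poly)
  if (check_simple && !polygon_is_simple(poly)) {
    wm_stop("wm_geometry_error", "polygon is self-intersecting (must be simple)")
  }
  cx <- bounds[1L] + (seq_len(ncol) - 0.5) * (bounds[3L] - bounds[1L]) / ncol
  cy <- bounds[2L] + (seq_len(nrow) - 0.5) * (bounds[4L] - bounds[2L]) / nrow
  px <- rep(cx, each = nrow)
  py <- rep(cy, times = ncol)
  matrix(as.integer(points_in_polygon(px, py, poly)), nrow = nrow, ncol = ncol)
}
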