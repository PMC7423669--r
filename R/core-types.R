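# Core domain types: landmark_set, color_spec, reference_frame,
# pattern_raster. All are lightweight S3 lists with validating constructors.

#' Ordered landmark set for one wing image
#'
#' Ordered 2D coordinates of homologous vein intersections in image pixel
#' coordinates (origin top-left, y increasing downward). The point order is
#' the homology correspondence: index i marks the same vein intersection on
#' every wing in a study.
#'
#' @param points Numeric K x 2 matrix (columns x, y).
#' @param image_id Identifier of the image the landmarks were digitized on.
#' @param k Expected landmark count (default 11, the standard forewing
#'   vein-intersection scheme); `NULL` skips the count check.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(points, image_id = "", k = 11L) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) {
    wm_stop("wm_landmark_error", "landmarks must have two columns (x, y)")
  }
  storage.mode(points) <- "double"
  if (!is.null(k) && nrow(points) != k) {
    wm_stop(
      "wm_landmark_count_error",
      sprintf("expected %d landmarks, got %d", k, nrow(points))
    )
  }
  if (anyNA(points) || any(!is.finite(points))) {
    wm_stop("wm_landmark_error", "landmark coordinates must be finite")
  }
  colnames(points) <- c("x", "y")
  structure(list(points = points, image_id = as.character(image_id)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set> %d landmarks, image '%s'\n", nrow(x$points), x$image_id
  ))
  invisible(x)
}

#' Colour specification for pattern extraction
#'
#' A target RGB colour plus a threshold fraction (the colour offset): a
#' pixel matches when every channel lies within `round(offset * 255)` of the
#' target (Chebyshev box threshold).
#'
#' @param name Label, e.g. "red", "yellow", "white".
#' @param rgb Numeric length-3 target colour, channels in [0, 255].
#' @param offset Threshold fraction in [0, 1].
#' @return Object of class `color_spec`.
#' @export
color_spec <- function(name, rgb, offset) {
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3L || any(rgb < 0) || any(rgb > 255)) {
    wm_stop("wm_config_error", "rgb must be three channel values in [0, 255]")
  }
  offset <- as.numeric(offset)
  if (length(offset) != 1L || is.na(offset) || offset < 0 || offset > 1) {
    wm_stop("wm_config_error", "offset must be a single value in [0, 1]")
  }
  structure(list(name = as.character(name), rgb = rgb, offset = offset),
            class = "color_spec")
}

#' Common reference frame for pattern rasters
#'
#' Defines the grid every pattern is aligned into: the landmarks of the
#' chosen reference sample, the raster bounds in reference pixel
#' coordinates, the grid resolution, and the wing outline used to mask
#' cells that are not wing.
#'
#' @param landmarks `landmark_set` of the reference sample.
#' @param wing_outline Simple polygon (vertex matrix) outlining the wing in
#'   reference pixel coordinates.
#' @param grid_shape Integer length-2 (rows, cols); default `c(150, 150)`.
#' @param bounds Numeric length-4 (xmin, ymin, xmax, ymax). Defaults to the
#'   landmark bounding box expanded by `expand` on each side.
#' @param expand Fractional bounding-box expansion used when `bounds` is
#'   missing (default 0.25 per side).
#' @return Object of class `reference_frame` with an `outline_mask` logical
#'   matrix marking within-wing cells.
#' @export
reference_frame <- function(landmarks, wing_outline, grid_shape = c(150L, 150L),
                            bounds = NULL, expand = 0.25) {
  stopifnot(inherits(landmarks, "landmark_set"))
  wing_outline <- as_polygon(wing_outline)
  if (!polygon_is_simple(wing_outline)) {
    wm_stop("wm_geometry_error", "wing outline must be a simple polygon")
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 2L)) {
    wm_stop("wm_config_error", "grid_shape must be at least (2, 2)")
  }
  pts <- landmarks$points
  if (is.null(bounds)) {
    rx <- range(pts[, 1L]); ry <- range(pts[, 2L])
    mx <- diff(rx) * expand; my <- diff(ry) * expand
    bounds <- c(rx[1L] - mx, ry[1L] - my, rx[2L] + mx, ry[2L] + my)
  }
  bounds <- as.numeric(bounds)
  if (length(bounds) != 4L || bounds[1L] >= bounds[3L] || bounds[2L] >= bounds[4L]) {
    wm_stop("wm_config_error", "bounds must be (xmin, ymin, xmax, ymax) with positive extent")
  }
  if (any(pts[, 1L] <= bounds[1L]) || any(pts[, 1L] >= bounds[3L]) ||
      any(pts[, 2L] <= bounds[2L]) || any(pts[, 2L] >= bounds[4L])) {
    wm_stop("wm_config_error", "bounds must strictly contain all reference landmarks")
  }
  outline_mask <- rasterize_polygon(wing_outline, grid_shape[1L], grid_shape[2L],
                                    bounds = bounds) == 1L
  frame_id <- sprintf(
    "frame[%dx%d|%.6g,%.6g,%.6g,%.6g]",
    grid_shape[1L], grid_shape[2L], bounds[1L], bounds[2L], bounds[3L], bounds[4L]
  )
  structure(
    list(
      landmarks = landmarks, grid_shape = grid_shape, bounds = bounds,
      wing_outline = wing_outline, outline_mask = outline_mask,
      frame_id = frame_id
    ),
    class = "reference_frame"
  )
}

#' @export
print.reference_frame <- function(x, ...) {
  cat(sprintf(
    "<reference_frame> %d x %d grid, bounds [%.1f, %.1f] x [%.1f, %.1f], %d/%d cells in wing\n",
    x$grid_shape[1L], x$grid_shape[2L], x$bounds[1L], x$bounds[3L],
    x$bounds[2L], x$bounds[4L], sum(x$outline_mask), length(x$outline_mask)
  ))
  invisible(x)
}

#' Cell-center coordinates of a reference frame
#'
#' @param frame A `reference_frame`.
#' @return List with `x` (length ncol) and `y` (length nrow) center
#'   coordinates; row 1 / y[1] is the top of the frame.
#' @export
cell_centers <- function(frame) {
  b <- frame$bounds; g <- frame$grid_shape
  list(
    x = b[1L] + (seq_len(g[2L]) - 0.5) * (b[3L] - b[1L]) / g[2L],
    y = b[2L] + (seq_len(g[1L]) - 0.5) * (b[4L] - b[2L]) / g[1L]
  )
}

#' Pattern raster in a common reference frame
#'
#' A grid of pattern values aligned to a reference frame. `kind` declares
#' the value semantics: `binary` (per-sample presence, values 0/1),
#' `frequency` (population presence proportion, [0, 1]) or `signed`
#' (difference or predicted pattern, [-1, 1]). Cells outside the wing
#' outline are `NA` (missing) and are never counted in areas.
#'
#' @param values Numeric matrix matching the frame's `grid_shape`; cells
#'   outside the wing outline are forced to `NA`.
#' @param kind One of `"binary"`, `"frequency"`, `"signed"`.
#' @param frame The `reference_frame`, or a frame_id string when the frame
#'   object is not at hand.
#' @return Object of class `pattern_raster`.
#' @export
pattern_raster <- function(values, kind = c("binary", "frequency", "signed"),
                           frame) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (inherits(frame, "reference_frame")) {
    if (!all(dim(values) == frame$grid_shape)) {
      wm_stop("wm_frame_mismatch_error", "raster dimensions do not match the frame grid")
    }
    values[!frame$outline_mask] <- NA_real_
    frame_id <- frame$frame_id
  } else {
    frame_id <- as.character(frame)
  }
  v <- values[!is.na(values)]
  ok <- switch(kind,
    binary = all(v %in% c(0, 1)),
    frequency = all(v >= 0 & v <= 1),
    signed = all(v >= -1 & v <= 1)
  )
  if (!ok) {
    wm_stop("wm_raster_error",
            sprintf("raster values out of range for kind '%s'", kind))
  }
  structure(list(values = values, kind = kind, frame_id = frame_id),
            class = "pattern_raster")
}

#' @export
print.pattern_raster <- function(x, ...) {
  cat(sprintf(
    "<pattern_raster> %s, %d x %d, %d non-missing cells\n",
    x$kind, nrow(x$values), ncol(x$values), sum(!is.na(x$values))
  ))
  invisible(x)
}

# internal: assert a list of rasters shares one frame, return frame_id
.common_frame <- function(rasters) {
  ids <- vapply(rasters, function(r) r$frame_id, character(1L))
  if (length(unique(ids)) != 1L) {
    wm_stop("wm_frame_mismatch_error", "rasters are not on a common reference frame")
  }
  ids[[1L]]
}

#' Rasterize a polygon into a reference frame
#'
#' Cell = 1 iff the cell center is inside the polygon (even-odd rule);
#' cells outside the wing outline are missing.
#'
#' @param polygon Simple polygon in reference coordinates.
#' @param frame A `reference_frame`.
#' @return Binary `pattern_raster`.
#' @export
polygon_to_mask <- function(polygon, frame) {
  stopifnot(inherits(frame, "reference_frame"))
  m <- rasterize_polygon(polygon, frame$grid_shape[1L], frame$grid_shape[2L],
                         bounds = frame$bounds)
  pattern_raster(m, "binary", frame)
}
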