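# Colour-pattern extraction: threshold an RGB wing image against target
# colours and mask out damaged regions.

#' Extract a binary colour-pattern mask from an RGB image
#'
#' A pixel matches a colour spec when its distance to the target colour is
#' within the spec's offset. The default metric is the Chebyshev
#' (max-channel) box: every channel within `round(offset * 255)` of the
#' target. `euclidean` instead thresholds the RGB Euclidean distance at
#' `offset * 255`. The returned mask is the union (logical OR) over all
#' specs, so multi-colour patterns (e.g. red plus white bands) extract as
#' one pattern.
#'
#' @param image Numeric array height x width x 3, values 0..255.
#' @param specs A `color_spec` or list of them; must be non-empty.
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @return Integer 0/1 matrix (height x width) in sample pixel space.
#' @export
extract_color <- function(image, specs, metric = c("chebyshev", "euclidean")) {
  metric <- match.arg(metric)
  if (inherits(specs, "color_spec")) specs <- list(specs)
  if (!length(specs)) {
    wm_stop("wm_config_error", "at least one colour spec is required")
  }
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L) {
    wm_stop("wm_config_error", "image must be an height x width x 3 RGB array")
  }
  h <- dim(image)[1L]; w <- dim(image)[2L]
  out <- matrix(FALSE, h, w)
  for (s in specs) {
    stopifnot(inherits(s, "color_spec"))
    if (metric == "chebyshev") {
      tol <- round(s$offset * 255)
      m <- abs(image[, , 1L] - s$rgb[1L]) <= tol &
        abs(image[, , 2L] - s$rgb[2L]) <= tol &
        abs(image[, , 3L] - s$rgb[3L]) <= tol
    } else {
      d2 <- (image[, , 1L] - s$rgb[1L])^2 +
        (image[, , 2L] - s$rgb[2L])^2 +
        (image[, , 3L] - s$rgb[3L])^2
      m <- d2 <= (s$offset * 255)^2
    }
    out <- out | m
  }
  matrix(as.integer(out), h, w)
}

#' Zero out excluded regions of a binary mask
#'
#' Forces pixels inside any exclusion polygon (damaged wing regions,
#' background noise co-extracted with the pattern) to 0; all other pixels
#' are unchanged. Idempotent.
#'
#' @param mask Binary matrix in sample pixel space.
#' @param polygons List of simple polygons in sample pixel coordinates
#'   (possibly empty).
#' @return Binary matrix of the same dimension.
#' @export
apply_exclusions <- function(mask, polygons) {
  mask <- as.matrix(mask)
  if (!length(polygons)) return(mask)
  if (is.matrix(polygons)) polygons <- list(polygons)
  h <- nrow(mask); w <- ncol(mask)
  for (poly in polygons) {
    excl <- rasterize_polygon(poly, h, w)
    mask[excl == 1L] <- 0L
  }
  mask
}
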