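# CRISPR-KO phenotype quantification: >=50% consensus pattern with traced
# contours, per-wing affected area vs. the wild-type consensus, and overlap
# of KO regions with wild-type difference maps.

#' Consensus KO pattern and contours
#'
#' Builds the KO pattern-frequency map, thresholds it into the consensus
#' pattern (cells present in at least `threshold` of the KO wings, default
#' 50%), and traces the consensus boundary as closed contours at the 0.5
#' isoline by marching squares with linear interpolation
#' (`grDevices::contourLines`). The grid is padded with a zero ring placed
#' on the frame bounds so every contour closes without leaving the frame.
#'
#' @param ko_rasters List (>= 2) of binary `pattern_raster`s from KO wings
#'   on a common frame.
#' @param threshold Consensus frequency threshold in (0, 1], default 0.5.
#' @param frame Optional `reference_frame`; required for contour coordinates
#'   (contours are skipped with a message when absent).
#' @return Object of class `ko_summary`: `ko_frequency` (frequency raster),
#'   `consensus` (binary raster), `contours` (list of closed x/y polyline
#'   lists in reference coordinates), `threshold`, `n_wings`.
#' @export
ko_consensus <- function(ko_rasters, threshold = 0.5, frame = NULL) {
  if (length(ko_rasters) < 2L) {
    wm_stop("wm_sample_size_error", "consensus needs at least 2 KO rasters")
  }
  if (threshold <= 0 || threshold > 1) {
    wm_stop("wm_config_error", "threshold must be in (0, 1]")
  }
  freq <- frequency_map(ko_rasters)
  cons_vals <- ifelse(is.na(freq$values), NA_real_,
                      as.numeric(freq$values >= threshold))
  consensus <- pattern_raster(cons_vals, "binary", freq$frame_id)
  contours <- list()
  if (!is.null(frame)) {
    contours <- trace_contours(consensus, frame)
  }
  structure(
    list(ko_frequency = freq, consensus = consensus, contours = contours,
         threshold = threshold, n_wings = length(ko_rasters)),
    class = "ko_summary"
  )
}

#' Trace closed 0.5-isoline contours of a binary raster
#'
#' @param raster Binary `pattern_raster` (missing cells treated as 0).
#' @param frame The `reference_frame` giving cell-center coordinates.
#' @param level Isoline level (default 0.5).
#' @return List of contours, each a list with closed `x`, `y` vertex
#'   vectors in reference coordinates.
#' @export
trace_contours <- function(raster, frame, level = 0.5) {
  stopifnot(inherits(frame, "reference_frame"))
  v <- raster$values
  v[is.na(v)] <- 0
  cc <- cell_centers(frame)
  # zero ring on the frame bounds: contours close and stay inside bounds
  x <- c(frame$bounds[1L], cc$x, frame$bounds[3L])
  y <- c(frame$bounds[2L], cc$y, frame$bounds[4L])
  z <- matrix(0, nrow(v) + 2L, ncol(v) + 2L)
  z[2:(nrow(v) + 1L), 2:(ncol(v) + 1L)] <- v
  # contourLines indexes z[i, j] at (x[i], y[j]): transpose row/col grid
  lines <- grDevices::contourLines(x = x, y = y, z = t(z), levels = level)
  lapply(lines, function(l) {
    n <- length(l$x)
    if (l$x[1L] != l$x[n] || l$y[1L] != l$y[n]) {
      l$x <- c(l$x, l$x[1L]); l$y <- c(l$y, l$y[1L])
    }
    list(x = l$x, y = l$y)
  })
}

#' Per-wing KO-affected area against the wild-type consensus
#'
#' For each KO wing, the affected region is the symmetric difference
#' between the wing's pattern and the wild-type consensus pattern,
#' restricted to the wing outline; its size is reported as a percentage of
#' within-outline cells, with the mean and sample standard deviation across
#' wings. Gain-only (pattern acquired by the KO) and loss-only (pattern
#' lost) sub-reports are included, since knockouts can both expand and
#' retract the pattern.
#'
#' @param ko_rasters List of binary `pattern_raster`s from KO wings.
#' @param wildtype_consensus Binary `pattern_raster`, the >= 50% consensus
#'   of the wild-type population (see [ko_consensus()]).
#' @return Object of class `ko_area_summary`: `per_wing`, `mean`, `sd` (in
#'   % of the forewing), and `gain` / `loss` sublists of the same shape.
#' @export
ko_affected_area <- function(ko_rasters, wildtype_consensus) {
  if (!length(ko_rasters)) {
    wm_stop("wm_sample_size_error", "at least one KO raster is required")
  }
  .common_frame(c(ko_rasters, list(wildtype_consensus)))
  wt <- wildtype_consensus$values
  inside <- !is.na(wt)
  n_in <- sum(inside)
  if (n_in == 0L) wm_stop("wm_config_error", "empty wing outline")
  stat3 <- function(per) {
    list(per_wing = per, mean = mean(per),
         sd = if (length(per) > 1L) stats::sd(per) else 0)
  }
  sym <- gain <- loss <- numeric(length(ko_rasters))
  for (i in seq_along(ko_rasters)) {
    ko <- ko_rasters[[i]]$values
    d_gain <- sum(ko[inside] == 1 & wt[inside] == 0)
    d_loss <- sum(ko[inside] == 0 & wt[inside] == 1)
    gain[i] <- 100 * d_gain / n_in
    loss[i] <- 100 * d_loss / n_in
    sym[i] <- gain[i] + loss[i]
  }
  out <- stat3(sym)
  out$gain <- stat3(gain)
  out$loss <- stat3(loss)
  class(out) <- "ko_area_summary"
  out
}

#' @export
print.ko_area_summary <- function(x, ...) {
  cat(sprintf(
    "<ko_area_summary> affected %.1f +/- %.1f%% of the forewing (gain %.1f%%, loss %.1f%%; n = %d wings)\n",
    x$mean, x$sd, x$gain$mean, x$loss$mean, length(x$per_wing)
  ))
  invisible(x)
}

#' Overlap between two wing regions
#'
#' Set arithmetic between two binary regions on the reference frame,
#' reported as percentages of the within-outline (forewing) area:
#' the intersection, and each region net of the other. A signed difference
#' map can stand in for either region by thresholding one sign (cells where
#' group A, or group B, shows consistently more pattern).
#'
#' @param region_a Binary `pattern_raster`.
#' @param region_b Binary or signed `pattern_raster`.
#' @param sign_b For a signed `region_b`: `"positive"` keeps cells > `tol`
#'   (more pattern in group A of the difference), `"negative"` keeps cells
#'   < -`tol`.
#' @param tol Threshold magnitude applied when `region_b` is signed
#'   (default 0.5: a majority-consistent difference).
#' @return List with `overlap_pct`, `a_only_pct`, `b_only_pct`,
#'   `area_a_pct`, `area_b_pct` (all % of the forewing).
#' @export
region_overlap <- function(region_a, region_b,
                           sign_b = c("positive", "negative"), tol = 0.5) {
  .common_frame(list(region_a, region_b))
  sign_b <- match.arg(sign_b)
  a <- region_a$values
  b <- region_b$values
  if (region_b$kind == "signed") {
    b <- ifelse(is.na(b), NA_real_,
                as.numeric(if (sign_b == "positive") b >= tol else b <= -tol))
  }
  inside <- !is.na(a) & !is.na(b)
  n_in <- sum(inside)
  if (n_in == 0L) wm_stop("wm_config_error", "empty wing outline")
  a <- a[inside] == 1; b <- b[inside] == 1
  list(
    overlap_pct = 100 * sum(a & b) / n_in,
    a_only_pct = 100 * sum(a & !b) / n_in,
    b_only_pct = 100 * sum(!a & b) / n_in,
    area_a_pct = 100 * sum(a) / n_in,
    area_b_pct = 100 * sum(b) / n_in
  )
}
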