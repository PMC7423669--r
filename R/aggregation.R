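# Population-level aggregation: pattern-frequency maps, co-mimic
# difference maps, relative pattern area and mismatch statistics.

#' Population pattern-frequency map
#'
#' Cellwise mean of binary per-sample rasters: the proportion of wings in
#' the population showing the pattern at each cell. Missing (outside-wing)
#' cells stay missing.
#'
#' @param rasters Non-empty list of binary `pattern_raster`s on a common
#'   frame.
#' @return `pattern_raster` of kind `frequency`.
#' @export
frequency_map <- function(rasters) {
  if (!length(rasters)) {
    wm_stop("wm_config_error", "at least one raster is required")
  }
  frame_id <- .common_frame(rasters)
  acc <- Reduce(`+`, lapply(rasters, function(r) r$values))
  pattern_raster(acc / length(rasters), "frequency", frame_id)
}

#' Difference map between two pattern-frequency maps
#'
#' Cellwise `f_A - f_B` in [-1, 1]. Sign convention: positive cells are more
#' present in group A (rendered red in previews), negative cells more
#' present in group B (blue).
#'
#' @param f_a,f_b Frequency `pattern_raster`s on the same frame.
#' @return `pattern_raster` of kind `signed`.
#' @export
difference_map <- function(f_a, f_b) {
  .common_frame(list(f_a, f_b))
  pattern_raster(f_a$values - f_b$values, "signed", f_a$frame_id)
}

#' Relative pattern area
#'
#' Proportion of the total wing area in which the pattern is observed:
#' the sum of raster values over within-wing cells divided by the count of
#' within-wing cells. Missing cells never count.
#'
#' @param raster Binary or frequency `pattern_raster`.
#' @param outline_mask Optional logical matrix restricting the wing region
#'   further; defaults to the raster's non-missing cells.
#' @return Proportion in [0, 1].
#' @export
relative_area <- function(raster, outline_mask = NULL) {
  stopifnot(inherits(raster, "pattern_raster"))
  v <- raster$values
  inside <- !is.na(v)
  if (!is.null(outline_mask)) inside <- inside & outline_mask
  n <- sum(inside)
  if (n == 0L) {
    wm_stop("wm_config_error", "empty wing outline: no cells to measure area over")
  }
  sum(v[inside]) / n
}

#' Mismatch statistics for a co-mimic pair
#'
#' Quantifies how two populations differ in pattern, separating position
#' from size. The absolute mismatch is the mean over within-wing cells of
#' `|f_A - f_B|` between the two frequency maps; it is sensitive to where
#' the pattern sits. The relative-area difference is
#' `|mean(area_A) - mean(area_B)|` of per-sample relative pattern areas; it
#' is blind to position. Both lie in [0, 1] and are directly comparable.
#' Per-sample mismatch values (each sample's binary raster against the other
#' group's frequency map, averaged over within-wing cells) are the
#' observation units for the one-sample t-test on absolute mismatch.
#'
#' @param group_a,group_b Lists (each >= 2) of binary `pattern_raster`s on a
#'   common frame.
#' @return Object of class `mismatch_summary` with fields
#'   `absolute_mismatch`, `relative_area_difference`, `per_sample_areas_a`,
#'   `per_sample_areas_b`, `per_sample_mismatch_a`, `per_sample_mismatch_b`,
#'   and the two frequency maps.
#' @export
mismatch_summary <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    wm_stop("wm_sample_size_error", "each group needs at least 2 rasters")
  }
  .common_frame(c(group_a, group_b))
  f_a <- frequency_map(group_a)
  f_b <- frequency_map(group_b)
  inside <- !is.na(f_a$values) & !is.na(f_b$values)
  absolute_mismatch <- mean(abs(f_a$values - f_b$values)[inside])
  areas_a <- vapply(group_a, relative_area, numeric(1L))
  areas_b <- vapply(group_b, relative_area, numeric(1L))
  mis_a <- vapply(group_a, function(r) {
    mean(abs(r$values - f_b$values)[inside])
  }, numeric(1L))
  mis_b <- vapply(group_b, function(r) {
    mean(abs(r$values - f_a$values)[inside])
  }, numeric(1L))
  structure(
    list(
      absolute_mismatch = absolute_mismatch,
      relative_area_difference = abs(mean(areas_a) - mean(areas_b)),
      per_sample_areas_a = areas_a,
      per_sample_areas_b = areas_b,
      per_sample_mismatch_a = mis_a,
      per_sample_mismatch_b = mis_b,
      frequency_a = f_a,
      frequency_b = f_b
    ),
    class = "mismatch_summary"
  )
}

#' @export
print.mismatch_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<mismatch_summary> n = %d + %d\n",
      "  absolute mismatch:        %.4f\n",
      "  relative-area difference: %.4f (areas %.4f vs %.4f)\n"
    ),
    length(x$per_sample_areas_a), length(x$per_sample_areas_b),
    x$absolute_mismatch, x$relative_area_difference,
    mean(x$per_sample_areas_a), mean(x$per_sample_areas_b)
  ))
  invisible(x)
}
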