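# PCA over flattened binary pattern rasters: per-sample scores, loading
# rasters, predicted-pattern reconstruction along axes, and axis selection.

#' PCA of aligned binary pattern rasters
#'
#' Flattens each raster over the within-wing cells (missing cells are
#' dropped from the feature vector, not zero-filled), centers by the
#' cellwise mean and decomposes by SVD of the sample x cell matrix — the
#' only tractable route when cells vastly outnumber samples. Axis signs are
#' fixed so each loading's largest-magnitude element is positive, making
#' results deterministic. Cells with zero variance across samples (pattern
#' present in all samples, or in none) carry exactly zero loading on every
#' axis: they contribute no variance.
#'
#' @param rasters List (>= 3) of binary `pattern_raster`s on a common frame.
#' @param ids Optional sample identifiers for score rows.
#' @return Object of class `raster_pca`: `mean_raster` (frequency raster),
#'   `scores` (n x r matrix), `explained_variance_ratio` (length r, sums to
#'   1 over axes with nonzero variance), `loadings` (cells x r, zero rows at
#'   zero-variance cells), plus the cell index and frame bookkeeping.
#' @export
fit_raster_pca <- function(rasters, ids = NULL) {
  if (length(rasters) < 3L) {
    wm_stop("wm_sample_size_error", "raster PCA needs at least 3 samples")
  }
  frame_id <- .common_frame(rasters)
  miss <- is.na(rasters[[1L]]$values)
  for (r in rasters) {
    if (!identical(is.na(r$values), miss)) {
      wm_stop("wm_frame_mismatch_error", "rasters disagree on missing cells")
    }
  }
  cell_idx <- which(!miss)
  x <- t(vapply(rasters, function(r) r$values[cell_idx],
                numeric(length(cell_idx))))
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  nz <- which(colSums(xc^2) > 0)
  r_max <- min(n - 1L, length(nz))
  loadings <- matrix(0, length(cell_idx), max(r_max, 0L))
  scores <- matrix(0, n, max(r_max, 0L))
  evr <- numeric(max(r_max, 0L))
  if (r_max > 0L) {
    sv <- svd(xc[, nz, drop = FALSE], nu = r_max, nv = r_max)
    d <- sv$d[seq_len(r_max)]
    # deterministic sign: largest-|.| loading element positive
    for (a in seq_len(r_max)) {
      v <- sv$v[, a]
      if (v[which.max(abs(v))] < 0) {
        sv$v[, a] <- -v
        sv$u[, a] <- -sv$u[, a]
      }
    }
    loadings[nz, ] <- sv$v
    scores <- sv$u %*% diag(d, r_max)
    evr <- d^2 / sum(sv$d^2)
  }
  if (is.null(ids)) ids <- paste0("sample_", seq_len(n))
  rownames(scores) <- ids
  mean_vals <- rasters[[1L]]$values
  mean_vals[cell_idx] <- mu
  structure(
    list(
      mean_raster = pattern_raster(mean_vals, "frequency", frame_id),
      loadings = loadings,
      scores = scores,
      explained_variance_ratio = evr,
      cell_index = cell_idx,
      grid_dim = dim(rasters[[1L]]$values),
      frame_id = frame_id,
      n_samples = n
    ),
    class = "raster_pca"
  )
}

#' @export
print.raster_pca <- function(x, ...) {
  cat(sprintf(
    "<raster_pca> %d samples, %d cells, %d axes; variance: %s\n",
    x$n_samples, length(x$cell_index), ncol(x$scores),
    paste(sprintf("%.1f%%", 100 * utils::head(x$explained_variance_ratio, 4L)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Loading of one PC axis as a signed raster
#'
#' @param model A `raster_pca`.
#' @param axis Axis index.
#' @return `pattern_raster` of kind `signed` (loadings rescaled to max
#'   magnitude 1 for display).
#' @export
loading_raster <- function(model, axis) {
  if (axis < 1L || axis > ncol(model$loadings)) {
    wm_stop("wm_config_error", sprintf("axis %d out of range", axis))
  }
  v <- rep(NA_real_, prod(model$grid_dim))
  load <- model$loadings[, axis]
  mx <- max(abs(load))
  v[model$cell_index] <- if (mx > 0) load / mx else load
  pattern_raster(matrix(v, model$grid_dim[1L], model$grid_dim[2L]),
                 "signed", model$frame_id)
}

#' Predicted pattern along one PC axis
#'
#' Reconstructs the predicted pattern deviation at a given score on one
#' axis, holding all other axes at zero: `score x loading_axis`. Positive
#' cells predict higher presence of the pattern (red in previews), negative
#' cells predict its absence (blue); cells whose pattern state is shared by
#' all samples have zero predicted value. Values are clipped to [-1, 1] for
#' display.
#'
#' @param model A `raster_pca`.
#' @param axis Axis index (must be a fitted axis).
#' @param score Score value along the axis (e.g. the min or max observed
#'   score to show the extremes of variation).
#' @return `pattern_raster` of kind `signed`.
#' @export
predict_pattern <- function(model, axis, score) {
  if (axis < 1L || axis > ncol(model$loadings)) {
    wm_stop("wm_config_error", sprintf("axis %d out of range", axis))
  }
  v <- rep(NA_real_, prod(model$grid_dim))
  v[model$cell_index] <- pmin(pmax(score * model$loadings[, axis], -1), 1)
  pattern_raster(matrix(v, model$grid_dim[1L], model$grid_dim[2L]),
                 "signed", model$frame_id)
}

#' Select significant PC axes
#'
#' `broken-stick` (default) retains the leading axes whose explained-
#' variance ratio exceeds the broken-stick null expectation — a standard,
#' parameter-free criterion for "significant" axes. `cumulative` retains
#' the smallest prefix of axes reaching `threshold` cumulative variance.
#' `fixed` retains the first `k` axes.
#'
#' @param model A `raster_pca`.
#' @param method `"broken-stick"`, `"cumulative"` or `"fixed"`.
#' @param threshold Cumulative-variance fraction for `cumulative`
#'   (default 0.9).
#' @param k Axis count for `fixed`.
#' @return Integer vector of retained axis indices (possibly empty).
#' @export
select_axes <- function(model, method = c("broken-stick", "cumulative", "fixed"),
                        threshold = 0.9, k = NULL) {
  method <- match.arg(method)
  evr <- model$explained_variance_ratio
  p <- length(evr)
  if (p == 0L) return(integer())
  if (method == "broken-stick") {
    bs <- rev(cumsum(1 / rev(seq_len(p)))) / p
    keep <- evr >= bs - 1e-10
    # leading run only: once an axis drops below the stick, stop
    first_fail <- which(!keep)
    upto <- if (length(first_fail)) first_fail[1L] - 1L else p
    return(seq_len(upto))
  }
  if (method == "cumulative") {
    if (is.na(threshold) || threshold <= 0 || threshold > 1) {
      wm_stop("wm_config_error", "threshold must be in (0, 1]")
    }
    cum <- cumsum(evr)
    idx <- which(cum >= threshold - 1e-12)
    upto <- if (length(idx)) idx[1L] else p
    return(seq_len(upto))
  }
  if (is.null(k) || k < 1L || k > p) {
    wm_stop("wm_config_error", "k must be between 1 and the number of axes")
  }
  seq_len(as.integer(k))
}
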