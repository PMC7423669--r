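# Thin-plate-spline registration: fit transforms between homologous
# landmark sets and resample sample-space binary masks into the common
# reference frame.

# TPS radial kernel U(r) = r^2 log r, with U(0) = 0.
.tps_kernel <- function(r) {
  u <- numeric(length(r))
  pos <- r > 0
  u[pos] <- r[pos]^2 * log(r[pos])
  dim(u) <- dim(r)
  u
}

.pairwise_dist <- function(a, b) {
  # a: n x 2, b: m x 2 -> n x m Euclidean distances
  d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
  sqrt(pmax(d2, 0))
}

#' Fit a thin-plate-spline transform between two landmark sets
#'
#' Solves the standard TPS linear system with kernel `U(r) = r^2 log(r)`
#' (`U(0) = 0`): for each output dimension, the mapped coordinate is an
#' affine part plus a weighted sum of kernel terms centered on the source
#' landmarks, subject to the three orthogonality side conditions
#' (sum(w) = 0, sum(w x) = 0, sum(w y) = 0). With `lambda = 0` the transform
#' interpolates the target landmarks exactly; `lambda > 0` adds smoothing on
#' the kernel diagonal for noisy landmarks, trading exactness for lower
#' bending energy.
#'
#' @param source,target `landmark_set`s (or K x 2 matrices) with the same
#'   point count K >= 3 and matching homology order.
#' @param lambda Regularization >= 0 (default 0: exact interpolation).
#' @return Object of class `tps_transform` with fields `affine` (3 x 2:
#'   constant, x, y coefficients per output dimension), `weights` (K x 2)
#'   and the landmark sets.
#' @export
fit_tps <- function(source, target, lambda = 0) {
  src <- if (inherits(source, "landmark_set")) source$points else as.matrix(source)
  tgt <- if (inherits(target, "landmark_set")) target$points else as.matrix(target)
  k <- nrow(src)
  if (nrow(tgt) != k) {
    wm_stop("wm_correspondence_error",
            sprintf("landmark counts differ: %d vs %d", k, nrow(tgt)))
  }
  if (k < 3L) {
    wm_stop("wm_correspondence_error", "at least 3 landmarks are required")
  }
  if (lambda < 0) wm_stop("wm_config_error", "lambda must be >= 0")
  if (anyDuplicated(src)) {
    wm_stop("wm_singular_error", "duplicate source landmarks make the TPS system singular")
  }
  kmat <- .tps_kernel(.pairwise_dist(src, src)) + diag(lambda, k)
  p <- cbind(1, src)
  l <- rbind(cbind(kmat, p), cbind(t(p), matrix(0, 3L, 3L)))
  rhs <- rbind(tgt, matrix(0, 3L, 2L))
  sol <- tryCatch(solve(l, rhs), error = function(e) {
    wm_stop("wm_singular_error",
            "TPS system is singular (collinear or duplicate source landmarks)")
  })
  structure(
    list(
      source = src, target = tgt,
      weights = sol[seq_len(k), , drop = FALSE],
      affine = sol[k + 1:3, , drop = FALSE],
      lambda = lambda
    ),
    class = "tps_transform"
  )
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("<tps_transform> %d landmarks, lambda = %g, max |warp weight| = %.3g\n",
              nrow(x$source), x$lambda, max(abs(x$weights))))
  invisible(x)
}

#' Apply a thin-plate-spline transform to points
#'
#' @param transform A fitted `tps_transform`.
#' @param points N x 2 matrix of (x, y) coordinates.
#' @return N x 2 matrix of transformed coordinates.
#' @export
evaluate_tps <- function(transform, points) {
  if (!inherits(transform, "tps_transform")) {
    wm_stop("wm_config_error", "transform must be a fitted tps_transform")
  }
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 2L) {
    points <- matrix(points, ncol = 2L)
  }
  u <- .tps_kernel(.pairwise_dist(points, transform$source))
  cbind(1, points) %*% transform$affine + u %*% transform$weights
}

#' Warp a sample-space binary mask into the reference frame
#'
#' Inverse-mapping resampling: a TPS is fitted with the reference landmarks
#' as source and the sample landmarks as target, evaluated at every
#' reference cell center, and the sample mask is looked up by nearest pixel
#' (lookups outside the image read 0). Inverse mapping leaves no holes and
#' nearest-pixel sampling keeps the mask binary without a second threshold.
#'
#' @param mask Binary matrix in sample pixel space (rows = image rows).
#' @param sample_landmarks `landmark_set` digitized on the sample image.
#' @param frame The `reference_frame`.
#' @param lambda TPS regularization passed to [fit_tps()].
#' @return Binary `pattern_raster` on the reference frame (cells outside the
#'   wing outline are missing).
#' @export
warp_mask_to_reference <- function(mask, sample_landmarks, frame, lambda = 0) {
  stopifnot(inherits(frame, "reference_frame"))
  mask <- as.matrix(mask)
  tr <- fit_tps(frame$landmarks, sample_landmarks, lambda = lambda)
  cc <- cell_centers(frame)
  g <- frame$grid_shape
  pts <- cbind(rep(cc$x, each = g[1L]), rep(cc$y, times = g[2L]))
  mapped <- evaluate_tps(tr, pts)
  # nearest pixel: point (x, y) in 0-based coords falls in pixel (floor+1)
  col <- floor(mapped[, 1L]) + 1L
  row <- floor(mapped[, 2L]) + 1L
  ok <- row >= 1L & row <= nrow(mask) & col >= 1L & col <= ncol(mask)
  v <- numeric(nrow(pts))
  v[ok] <- mask[cbind(row[ok], col[ok])]
  v[is.na(v)] <- 0
  pattern_raster(matrix(v, g[1L], g[2L]), "binary", frame)
}
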