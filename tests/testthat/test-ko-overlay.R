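# ko_overlay module: consensus patterns, contours, affected areas and
# region overlap.

test_that("consensus of identical rasters is that raster; votes follow the threshold", {
  frame <- make_open_frame(20L)
  set.seed(26)
  r <- random_binary_raster(frame, 0.3)
  res <- ko_consensus(rep(list(r), 5L), frame = frame)
  expect_identical(res$consensus$values, r$values)
  # a cell present in 4 of 10 wings is excluded (0.4 < 0.5)
  v0 <- matrix(0, 20, 20)
  v1 <- v0; v1[5, 5] <- 1
  rasters <- c(rep(list(pattern_raster(v1, "binary", frame)), 4L),
               rep(list(pattern_raster(v0, "binary", frame)), 6L))
  res4 <- ko_consensus(rasters, frame = frame)
  expect_equal(res4$consensus$values[5, 5], 0)
  # at 5 of 10 it is included (0.5 >= 0.5)
  rasters5 <- c(rep(list(pattern_raster(v1, "binary", frame)), 5L),
                rep(list(pattern_raster(v0, "binary", frame)), 5L))
  expect_equal(ko_consensus(rasters5)$consensus$values[5, 5], 1)
  expect_error(ko_consensus(rasters[1]), class = "wm_sample_size_error")
})

test_that("consensus equals the brute-force per-cell vote oracle and is monotone in threshold", {
  frame <- make_open_frame(32L)
  set.seed(27)
  rasters <- lapply(1:10, function(i) random_binary_raster(frame))
  counts <- Reduce(`+`, lapply(rasters, function(r) r$values))
  res <- ko_consensus(rasters, threshold = 0.5)
  expect_identical(res$consensus$values, (counts >= 5) * 1)
  res7 <- ko_consensus(rasters, threshold = 0.7)
  expect_true(all(res7$consensus$values <= res$consensus$values, na.rm = TRUE))
})

test_that("contours close, stay in bounds, and enclose the consensus support", {
  frame <- make_wing_frame(c(80L, 80L))
  v <- matrix(0, 80, 80)
  v[30:50, 35:55] <- 1
  r <- pattern_raster(v, "binary", frame)
  res <- ko_consensus(rep(list(r), 3L), frame = frame)
  expect_gt(length(res$contours), 0)
  total_area <- 0
  for (ct in res$contours) {
    n <- length(ct$x)
    expect_equal(c(ct$x[1], ct$y[1]), c(ct$x[n], ct$y[n]))
    expect_true(all(ct$x >= frame$bounds[1] & ct$x <= frame$bounds[3]))
    expect_true(all(ct$y >= frame$bounds[2] & ct$y <= frame$bounds[4]))
    total_area <- total_area + abs(polygon_area(cbind(ct$x, ct$y)))
  }
  # shoelace contour area agrees with the cell count within a one-cell
  # perimeter band
  cellsize <- (frame$bounds[3] - frame$bounds[1]) / 80 *
    (frame$bounds[4] - frame$bounds[2]) / 80
  n_cells <- sum(res$consensus$values == 1, na.rm = TRUE)
  perim_cells <- 4 * 22  # perimeter of the 21 x 21 block, generous band
  expect_lt(abs(total_area / cellsize - n_cells), perim_cells)
  # every consensus cell center lies inside some contour
  cc <- cell_centers(frame)
  idx <- which(res$consensus$values == 1, arr.ind = TRUE)
  pts <- cbind(cc$x[idx[, 2]], cc$y[idx[, 1]])
  inside <- rep(FALSE, nrow(pts))
  for (ct in res$contours) {
    inside <- inside | points_in_polygon(pts[, 1], pts[, 2], cbind(ct$x, ct$y))
  }
  expect_gte(mean(inside), 0.95)
})

test_that("affected area: trivial cases and duplication invariance", {
  frame <- make_wing_frame(c(50L, 50L))
  n_in <- sum(frame$outline_mask)
  base <- matrix(0, 50, 50)
  idx <- which(frame$outline_mask)
  base[idx[100:220]] <- 1
  wt <- pattern_raster(base, "binary", frame)
  # KO identical to the wild-type consensus: 0 +/- 0
  same <- ko_affected_area(rep(list(wt), 4L), wt)
  expect_equal(same$mean, 0)
  expect_equal(same$sd, 0)
  # each wing adds the same 30 cells: 100 * 30 / n_in, sd 0
  added <- base
  added[idx[500:529]] <- 1
  ko <- pattern_raster(added, "binary", frame)
  res <- ko_affected_area(rep(list(ko), 5L), wt)
  expect_equal(res$mean, 100 * 30 / n_in)
  expect_equal(res$sd, 0)
  expect_equal(res$gain$mean, res$mean)
  expect_equal(res$loss$mean, 0)
  # duplicating every wing leaves the mean unchanged
  set.seed(28)
  kos <- lapply(1:6, function(i) random_binary_raster(frame, 0.3))
  r1 <- ko_affected_area(kos, wt)
  r2 <- ko_affected_area(c(kos, kos), wt)
  expect_equal(r1$mean, r2$mean)
})

test_that("region_overlap matches brute-force set arithmetic", {
  frame <- make_open_frame(32L)
  set.seed(29)
  a <- random_binary_raster(frame, 0.4)
  b <- random_binary_raster(frame, 0.4)
  res <- region_overlap(a, b)
  av <- a$values == 1; bv <- b$values == 1
  n <- length(av)
  expect_equal(res$overlap_pct, 100 * sum(av & bv) / n)
  expect_equal(res$a_only_pct, 100 * sum(av & !bv) / n)
  expect_equal(res$b_only_pct, 100 * sum(!av & bv) / n)
  same <- region_overlap(a, a)
  expect_equal(same$overlap_pct, same$area_a_pct)
  expect_equal(same$a_only_pct, 0)
  # disjoint regions
  v1 <- matrix(0, 32, 32); v1[1:10, ] <- 1
  v2 <- matrix(0, 32, 32); v2[20:30, ] <- 1
  disj <- region_overlap(pattern_raster(v1, "binary", frame),
                         pattern_raster(v2, "binary", frame))
  expect_equal(disj$overlap_pct, 0)
})

test_that("signed difference maps threshold by sign in region_overlap", {
  frame <- make_open_frame(16L)
  v <- matrix(0, 16, 16)
  v[, 1:8] <- 0.8; v[, 9:16] <- -0.8
  dm <- pattern_raster(v, "signed", frame)
  a <- matrix(0, 16, 16); a[, 1:4] <- 1
  ar <- pattern_raster(a, "binary", frame)
  pos <- region_overlap(ar, dm, sign_b = "positive")
  expect_equal(pos$overlap_pct, 100 * 64 / 256)
  neg <- region_overlap(ar, dm, sign_b = "negative")
  expect_equal(neg$overlap_pct, 0)
})

test_that("synthetic KO population recovers the known affected region", {
  kp <- generate_ko_pair(make_quiet_spec(), 4, 6, seed = 31,
                         ko_area_fraction = 0.15)
  frame <- population_frame(kp$wildtype, pixel = TRUE)
  rw <- align_population(kp$wildtype, frame)
  rk <- align_population(kp$ko, frame, specs = morph_color_specs(kp$ko$spec))
  wt_cons <- ko_consensus(rw, frame = frame)$consensus
  res <- ko_affected_area(rk, wt_cons)
  truth_pct <- 100 * kp$ko$truth$ko_area_fraction
  expect_lt(abs(res$mean - truth_pct) / truth_pct, 0.10)
  # consensus contour encloses >= 95% of the true region
  ko_cons <- ko_consensus(rk, frame = frame)
  tr <- truth_raster(kp$ko, frame, which = "ko")
  cc <- cell_centers(frame)
  idx <- which(tr$values == 1, arr.ind = TRUE)
  pts <- cbind(cc$x[idx[, 2]], cc$y[idx[, 1]])
  inside <- rep(FALSE, nrow(pts))
  for (ct in ko_cons$contours) {
    inside <- inside | points_in_polygon(pts[, 1], pts[, 2], cbind(ct$x, ct$y))
  }
  expect_gte(mean(inside), 0.95)
})
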