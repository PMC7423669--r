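# Shared fixtures: small frames, random rasters and landmark configurations
# built in code.

# a frame whose outline covers every grid cell (square grid oracle tests)
make_open_frame <- function(n = 32L) {
  s <- n / 32
  lms <- landmark_set(cbind(
    x = c(4, 10, 16, 22, 28, 27, 16, 5, 10, 16, 22) * s,
    y = c(16, 5, 4, 5, 16, 27, 28, 27, 16, 17, 16) * s
  ), image_id = "ref")
  reference_frame(
    lms,
    wing_outline = cbind(x = c(-1, n + 1, n + 1, -1), y = c(-1, -1, n + 1, n + 1)),
    grid_shape = c(n, n), bounds = c(0, 0, n, n)
  )
}

# a frame with a genuine wing-like outline (some cells missing)
make_wing_frame <- function(grid = c(60L, 60L)) {
  pop <- generate_population(make_quiet_spec(), 1L, seed = 99L)
  population_frame(pop, grid_shape = grid)
}

# morph spec with zero jitter/noise (deterministic rendering)
make_quiet_spec <- function(archetype = "postman", ...) {
  morph_spec(archetype, jitter_sd = 0, warp_amplitude = 0, noise_sd = 0, ...)
}

random_binary_raster <- function(frame, p = 0.5) {
  g <- frame$grid_shape
  v <- matrix(as.numeric(stats::runif(prod(g)) < p), g[1L], g[2L])
  pattern_raster(v, "binary", frame)
}

# non-degenerate random landmark configuration
random_landmarks <- function(k = 11L, spread = 100) {
  repeat {
    pts <- cbind(stats::runif(k, 0, spread), stats::runif(k, 0, spread))
    if (qr(cbind(1, pts))$rank == 3L && !anyDuplicated(round(pts, 6))) {
      return(pts)
    }
  }
}
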