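# core module: landmark IO, polygon rasterization, frame/raster types,
# manifest and raster serialization.

test_that("CSV landmark files parse in file order and round-trip", {
  pts <- cbind(x = seq(10, 110, by = 10), y = seq(5, 105, by = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(landmark_set(pts, "w1"), path, dialect = "csv")
  lm <- read_landmarks(path, dialect = "csv")
  expect_s3_class(lm, "landmark_set")
  expect_equal(unname(lm$points), unname(pts))
})

test_that("tps-classic landmarks are y-flipped using image height and round-trip", {
  # y-up point (10, 20) in a 600-px-high image is image row y = 580
  path <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "10 20", "50 300", "200 599", "ID=wing_a"), path)
  lm <- read_landmarks(path, dialect = "tps", image_height = 600, k = 3)
  expect_equal(unname(lm$points[1L, ]), c(10, 580))
  expect_equal(unname(lm$points[3L, ]), c(200, 1))
  expect_equal(lm$image_id, "wing_a")
  out <- withr::local_tempfile(fileext = ".tps")
  write_landmarks(lm, out, dialect = "tps", image_height = 600)
  back <- read_landmarks(out, dialect = "tps", image_height = 600, k = 3)
  expect_equal(back$points, lm$points)
})

test_that("landmark count and parse errors are reported precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", sprintf("%d,%d", 1:10, 1:10)), path)
  expect_error(read_landmarks(path, "csv", k = 11), "expected 11 landmarks, got 10",
               class = "wm_landmark_count_error")
  writeLines(c("x,y", "1,2", "3,oops", "5,6"), path)
  err <- expect_error(read_landmarks(path, "csv", k = 3), class = "wm_parse_error")
  expect_match(conditionMessage(err), "line 3")
})

test_that("polygon_to_mask handles full-cover, degenerate and half-cover polygons", {
  frame <- make_open_frame(10L)
  full <- polygon_to_mask(cbind(c(-1, 11, 11, -1), c(-1, -1, 11, 11)), frame)
  expect_true(all(full$values == 1, na.rm = TRUE))
  degen <- polygon_to_mask(cbind(c(3, 3, 3), c(1, 5, 9)), frame)
  expect_true(all(degen$values == 0, na.rm = TRUE))
  # left half of a 10x10 grid: 50 cell centers, verified by brute force below
  left <- polygon_to_mask(cbind(c(0, 5, 5, 0), c(0, 0, 10, 10)), frame)
  expect_equal(sum(left$values), 50)
  centers <- expand.grid(x = seq_len(10) - 0.5, y = seq_len(10) - 0.5)
  expect_equal(sum(centers$x < 5), 50)
})

test_that("point-in-polygon agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  set.seed(11)
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  poly <- cbind(10 + (4 + 3 * runif(12)) * cos(t), 10 + (4 + 3 * runif(12)) * sin(t))
  px <- runif(400, 0, 20); py <- runif(400, 0, 20)
  ours <- points_in_polygon(px, py, poly)
  ref <- mgcv::in.out(rbind(poly, poly[1L, ]), cbind(px, py))
  expect_equal(ours, ref)
})

test_that("polygon_to_mask is monotone under polygon containment", {
  frame <- make_open_frame(20L)
  for (half in c(4, 8, 12, 16)) {
    inner <- cbind(c(10 - half / 2, 10 + half / 2, 10 + half / 2, 10 - half / 2),
                   c(10 - half / 2, 10 - half / 2, 10 + half / 2, 10 + half / 2))
    outer <- cbind(c(10 - half / 2 - 2, 10 + half / 2 + 2, 10 + half / 2 + 2, 10 - half / 2 - 2),
                   c(10 - half / 2 - 2, 10 - half / 2 - 2, 10 + half / 2 + 2, 10 + half / 2 + 2))
    m1 <- polygon_to_mask(inner, frame)$values
    m2 <- polygon_to_mask(outer, frame)$values
    expect_true(all(m1 <= m2, na.rm = TRUE))
  }
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_false(polygon_is_simple(bowtie))
  frame <- make_open_frame(10L)
  expect_error(polygon_to_mask(bowtie, frame), class = "wm_geometry_error")
})

test_that("pattern_raster enforces kind ranges and masks outside-outline cells", {
  frame <- make_wing_frame(c(40L, 40L))
  v <- matrix(1, 40, 40)
  r <- pattern_raster(v, "binary", frame)
  expect_true(all(is.na(r$values[!frame$outline_mask])))
  expect_error(pattern_raster(matrix(2, 40, 40), "binary", frame),
               class = "wm_raster_error")
  expect_error(pattern_raster(matrix(-0.5, 40, 40), "frequency", frame),
               class = "wm_raster_error")
})

test_that("raster CSV and polygon files round-trip", {
  frame <- make_wing_frame(c(30L, 30L))
  set.seed(5)
  r <- random_binary_raster(frame)
  path <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(r, path)
  back <- read_raster_csv(path, "binary", frame)
  expect_equal(back$values, r$values)
  poly <- cbind(x = c(1.5, 8, 6.25), y = c(2, 3, 9))
  ppath <- withr::local_tempfile(fileext = ".csv")
  write_polygon(poly, ppath)
  expect_equal(read_polygon(ppath), as.matrix(as.data.frame(poly)))
})

test_that("PNG images round-trip through write/read at 8-bit precision", {
  img <- array(sample(0:255, 20 * 30 * 3, replace = TRUE), c(20, 30, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_image(img, path)
  expect_equal(read_image(path), img, ignore_attr = TRUE)
})

test_that("manifest reading validates columns and vocabulary", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    image_id = c("a", "b"), species = "sp", morph = "postman",
    sex = "male", wing_side = "left", genotype = c("wild-type", "mutant"),
    image = "a.png", landmarks = "a.csv", masks = ""
  )
  utils::write.csv(df, path, row.names = FALSE)
  m <- read_manifest(path)
  expect_equal(nrow(m), 2L)
  err <- expect_error(
    read_manifest(path, vocab = list(genotype = c("wild-type", "KO"))),
    class = "wm_config_error"
  )
  expect_match(conditionMessage(err), "row 2")
})

test_that("reference_frame rejects bounds not containing the landmarks", {
  lms <- landmark_set(cbind(seq(2, 52, by = 5), seq(2, 52, by = 5)), k = 11)
  outline <- cbind(c(0, 60, 60, 0), c(0, 0, 60, 60))
  expect_error(
    reference_frame(lms, outline, bounds = c(10, 10, 60, 60)),
    class = "wm_config_error"
  )
  expect_error(
    reference_frame(lms, outline, grid_shape = c(1, 5)),
    class = "wm_config_error"
  )
})
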