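# Readers/writers: landmark files (CSV and classic morphometrics TPS),
# polygons (CSV vertex list or GeoJSON-style ring), RGB images
# (PNG/JPEG/TIFF), the sample manifest, and raster serialization.

#' Read a landmark file
#'
#' Two dialects are supported. `csv`: a header `x,y` followed by one row per
#' landmark, already in image pixel coordinates (origin top-left, y down).
#' `tps`: the classic morphometrics TPS text format (`LM=K` followed by
#' `x y` pairs), whose convention is y-up from the bottom-left corner; these
#' coordinates are flipped to the image convention using the image height
#' (`y_image = image_height - y_tps`).
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tps"`.
#' @param image_height Image height in pixels; required for the `tps`
#'   dialect to flip the y axis.
#' @param k Expected landmark count (default 11); `NULL` to accept any.
#' @param image_id Identifier stored on the result (default: file name).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, dialect = c("csv", "tps"), image_height = NULL,
                           k = 11L, image_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    wm_stop("wm_io_error", sprintf("landmark file not found: %s", path))
  }
  if (is.null(image_id)) image_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "csv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    body <- lines[-1L]  # header x,y
    pts <- matrix(NA_real_, length(body), 2L)
    for (i in seq_along(body)) {
      tok <- strsplit(trimws(body[[i]]), ",")[[1L]]
      val <- suppressWarnings(as.numeric(tok))
      if (length(val) != 2L || anyNA(val)) {
        wm_stop("wm_parse_error",
                sprintf("%s: non-numeric landmark at line %d", path, i + 1L))
      }
      pts[i, ] <- val
    }
    return(landmark_set(pts, image_id = image_id, k = k))
  }
  # classic TPS dialect
  lines <- readLines(path, warn = FALSE)
  lm_line <- grep("^LM\\s*=", lines)
  if (length(lm_line) != 1L) {
    wm_stop("wm_parse_error", sprintf("%s: expected exactly one LM= line", path))
  }
  n_pts <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", lines[lm_line])))
  if (is.na(n_pts)) {
    wm_stop("wm_parse_error",
            sprintf("%s: non-numeric LM count at line %d", path, lm_line))
  }
  if (is.null(image_height)) {
    wm_stop("wm_config_error",
            "image_height is required to flip tps y-up coordinates to image convention")
  }
  pts <- matrix(NA_real_, n_pts, 2L)
  for (i in seq_len(n_pts)) {
    ln <- lm_line + i
    if (ln > length(lines)) {
      wm_stop("wm_parse_error", sprintf("%s: file ends before point %d", path, i))
    }
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 2L || anyNA(val)) {
      wm_stop("wm_parse_error",
              sprintf("%s: non-numeric landmark at line %d", path, ln))
    }
    pts[i, ] <- val
  }
  pts[, 2L] <- image_height - pts[, 2L]
  id_line <- grep("^(ID|IMAGE)\\s*=", lines, value = TRUE)
  if (length(id_line)) image_id <- sub("^(ID|IMAGE)\\s*=\\s*", "", id_line[[1L]])
  landmark_set(pts, image_id = image_id, k = k)
}

#' Write a landmark file
#'
#' Inverse of [read_landmarks()] for both dialects; for `tps`, coordinates
#' are flipped back to y-up using `image_height`.
#'
#' @param landmarks A `landmark_set`.
#' @param path Output path.
#' @param dialect `"csv"` or `"tps"`.
#' @param image_height Image height in pixels (required for `tps`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, dialect = c("csv", "tps"),
                            image_height = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(landmarks, "landmark_set"))
  pts <- landmarks$points
  if (dialect == "csv") {
    writeLines(c("x,y", sprintf("%.10g,%.10g", pts[, 1L], pts[, 2L])), path)
  } else {
    if (is.null(image_height)) {
      wm_stop("wm_config_error", "image_height is required for the tps dialect")
    }
    writeLines(c(
      sprintf("LM=%d", nrow(pts)),
      sprintf("%.10g %.10g", pts[, 1L], image_height - pts[, 2L]),
      sprintf("ID=%s", landmarks$image_id)
    ), path)
  }
  invisible(path)
}

#' Read a polygon file
#'
#' CSV vertex list (header `x,y`) or a GeoJSON-style file carrying a
#' `Polygon` geometry (the exterior ring is used).
#'
#' @param path File path; `.json` / `.geojson` extensions select GeoJSON.
#' @return Polygon vertex matrix.
#' @export
read_polygon <- function(path) {
  if (!file.exists(path)) {
    wm_stop("wm_io_error", sprintf("polygon file not found: %s", path))
  }
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    g <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(g$geometry)) g <- g$geometry  # Feature wrapper
    if (is.null(g$coordinates)) {
      wm_stop("wm_parse_error", sprintf("%s: no polygon coordinates found", path))
    }
    ring <- g$coordinates
    if (is.list(ring)) ring <- ring[[1L]]
    if (length(dim(ring)) == 3L) ring <- ring[1L, , ]
    return(as_polygon(ring))
  }
  df <- utils::read.csv(path)
  as_polygon(as.matrix(df[, c("x", "y")]))
}

#' Write a polygon as a CSV vertex list
#'
#' @param poly Polygon vertex matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygon <- function(poly, path) {
  poly <- as_polygon(poly)
  utils::write.csv(as.data.frame(poly), path, row.names = FALSE)
  invisible(path)
}

#' Read an RGB wing image
#'
#' Reads PNG, JPEG or TIFF into an 8-bit RGB array. Grayscale images are
#' replicated across channels; an alpha channel is ignored.
#'
#' @param path Image path; format chosen by extension.
#' @return Numeric array height x width x 3 with values in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    wm_stop("wm_io_error", sprintf("image file not found: %s", path))
  }
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    wm_stop("wm_io_error", sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) img <- array(img[, , 1L], c(dim(img)[1:2], 3L))
  round(img * 255)
}

#' Write an 8-bit RGB array as a PNG image
#'
#' @param image Array height x width x 3, values 0..255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Read a sample manifest
#'
#' CSV with columns `image_id, species, morph, sex, wing_side, genotype,
#' image, landmarks, masks`; `masks` is a `;`-separated list of exclusion
#' polygon paths (possibly empty).
#'
#' @param path Manifest CSV path.
#' @param vocab Optional named list of allowed values, e.g.
#'   `list(genotype = c("wild-type", "KO"))`; violations raise an error
#'   naming the offending row.
#' @return Data frame, one row per sample, class `wing_manifest`.
#' @export
read_manifest <- function(path, vocab = NULL) {
  if (!file.exists(path)) {
    wm_stop("wm_io_error", sprintf("manifest file not found: %s", path))
  }
  m <- utils::read.csv(path, colClasses = "character")
  req <- c("image_id", "species", "morph", "sex", "wing_side", "genotype",
           "image", "landmarks", "masks")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols)) {
    wm_stop("wm_parse_error",
            sprintf("%s: manifest lacks columns: %s", path,
                    paste(missing_cols, collapse = ", ")))
  }
  for (col in names(vocab)) {
    bad <- which(!(m[[col]] %in% vocab[[col]]))
    if (length(bad)) {
      wm_stop("wm_config_error",
              sprintf("manifest row %d: %s '%s' not in declared vocabulary",
                      bad[1L], col, m[[col]][bad[1L]]))
    }
  }
  class(m) <- c("wing_manifest", "data.frame")
  m
}

#' Serialize a pattern raster to CSV
#'
#' Plain grid of values, `NA` for missing cells, row 1 = top of the frame.
#'
#' @param raster A `pattern_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "pattern_raster"))
  utils::write.table(raster$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a pattern raster from CSV
#'
#' @param path CSV grid written by [write_raster_csv()].
#' @param kind Raster kind (`binary`, `frequency`, `signed`).
#' @param frame `reference_frame` or frame_id string.
#' @return A `pattern_raster`.
#' @export
read_raster_csv <- function(path, kind, frame) {
  v <- as.matrix(utils::read.table(path, sep = ",", na.strings = "NA"))
  dimnames(v) <- NULL
  pattern_raster(v, kind, frame)
}

#' Write a PNG preview of a pattern raster
#'
#' Binary/frequency rasters map 0..1 to a white-to-blue ramp; signed rasters
#' use a diverging blue-white-red map with red for positive values (more
#' pattern in group A) and blue for negative. Missing cells render grey.
#'
#' @param raster A `pattern_raster`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(raster, path) {
  stopifnot(inherits(raster, "pattern_raster"))
  v <- raster$values
  h <- nrow(v); w <- ncol(v)
  img <- array(0.85, c(h, w, 3L))  # grey background for missing cells
  ok <- !is.na(v)
  if (raster$kind == "signed") {
    pos <- pmax(v, 0); neg <- pmax(-v, 0)
    r <- 1 - neg; g <- 1 - pos - neg; b <- 1 - pos
  } else {
    r <- 1 - v; g <- 1 - v; b <- rep(1, length(v))
    dim(r) <- dim(g) <- dim(b) <- dim(v)
  }
  ch <- list(r, g, b)
  for (k in 1:3) {
    plane <- img[, , k]
    plane[ok] <- pmin(pmax(ch[[k]][ok], 0), 1)
    img[, , k] <- plane
  }
  png::writePNG(img, path)
  invisible(path)
}
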