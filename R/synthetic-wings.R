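# Synthetic wing-image generator with known ground truth.
#
# Renders populations of forewing images that emulate the study inputs:
# a smooth wing outline, 11 vein-intersection landmarks, a mid-forewing
# band (MFB) of one of three archetypes (solid "postman" band, "split"
# two-spot, "broken" multi-spot), per-individual smooth spatial jitter,
# pixel noise and optional damage blotches, plus paired KO populations
# whose band is expanded by a known region. Rendering is flat-colour with
# hard edges: the downstream pipeline thresholds colours, so scale-level
# texture realism would add nothing testable.

# fixed normalized wing geometry (unit = wing length; y down)
.wing_outline_norm <- function(n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(
    x = 0.5 + 0.47 * cos(t),
    y = 0.34 + 0.30 * sin(t) * (1 - 0.25 * cos(t))
  )
}

.wing_landmarks_norm <- function() {
  rbind(
    c(0.07, 0.34),                                # wing base
    c(0.25, 0.12), c(0.50, 0.09), c(0.75, 0.14),  # anterior margin veins
    c(0.93, 0.31),                                # apex
    c(0.77, 0.52), c(0.53, 0.58), c(0.30, 0.55),  # posterior margin veins
    c(0.33, 0.33), c(0.54, 0.35), c(0.72, 0.32)   # interior vein crossings
  )
}

.ellipse_poly <- function(cx, cy, rx, ry, n = 40L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + rx * cos(t), y = cy + ry * sin(t))
}

# default flat-colour palette; all pairs > 2 x (offset * 255) apart in
# Chebyshev distance for the default extraction offset 0.15
.default_palette <- function() {
  list(
    background = c(120, 150, 120),
    wing = c(10, 10, 10),
    red = c(220, 40, 40),
    white = c(250, 250, 250),
    yellow = c(235, 200, 60),
    damage = c(150, 60, 150)
  )
}

#' Morph specification for the synthetic wing generator
#'
#' Describes one colour-pattern morph: the band archetype and its geometry
#' (in normalized wing coordinates, unit = wing length), the rendering
#' palette, and the per-individual variation model. Defaults emulate a
#' typical study population: modest landmark digitization noise, a smooth
#' individual warp, light pixel noise, no damage.
#'
#' @param archetype `"postman"` (solid band), `"split"` (two spots, white +
#'   red) or `"broken"` (three yellow spots).
#' @param band_center Band center along the wing length (fraction, default
#'   0.52).
#' @param band_width Band width as a fraction of wing length (default 0.18).
#' @param band_offset Positional shift of the whole band along the wing
#'   (fraction of wing length; used for co-mimic mismatch designs).
#' @param jitter_sd Landmark digitization noise sd in pixels (default 1.5).
#' @param warp_amplitude Amplitude (pixels) of the per-individual smooth
#'   TPS warp applied jointly to outline, band and landmarks (default 3).
#' @param noise_sd Gaussian pixel-noise sd on each channel (default 4).
#' @param damage_rate Probability that an individual carries a damage blotch
#'   recorded as an exclusion polygon (default 0).
#' @param ko_region Optional polygon (normalized coordinates) unioned into
#'   the band, emulating a knockout expansion of the pattern.
#' @param image_size Image (height, width) in pixels (default 140 x 200).
#' @param extract_offset Colour threshold the generator's ground-truth
#'   colour specs carry (default 0.15).
#' @param palette Named list of RGB triplets (background, wing, red, white,
#'   yellow, damage); all colours must be separated by more than twice the
#'   extraction offset in Chebyshev distance.
#' @return Object of class `morph_spec`.
#' @export
morph_spec <- function(archetype = c("postman", "split", "broken"),
                       band_center = 0.52, band_width = 0.18,
                       band_offset = 0, jitter_sd = 1.5, warp_amplitude = 3,
                       noise_sd = 4, damage_rate = 0, ko_region = NULL,
                       image_size = c(140L, 200L), extract_offset = 0.15,
                       palette = .default_palette()) {
  archetype <- match.arg(archetype)
  pal <- do.call(rbind, palette)
  sep <- 2 * extract_offset * 255
  for (i in seq_len(nrow(pal) - 1L)) {
    for (j in seq.int(i + 1L, nrow(pal))) {
      if (max(abs(pal[i, ] - pal[j, ])) <= sep) {
        wm_stop("wm_config_error", sprintf(
          "palette colours '%s' and '%s' are closer than twice the extraction offset",
          rownames(pal)[i], rownames(pal)[j]
        ))
      }
    }
  }
  spec <- structure(
    list(
      archetype = archetype, band_center = band_center,
      band_width = band_width, band_offset = band_offset,
      jitter_sd = jitter_sd, warp_amplitude = warp_amplitude,
      noise_sd = noise_sd, damage_rate = damage_rate, ko_region = ko_region,
      image_size = as.integer(image_size), extract_offset = extract_offset,
      palette = palette
    ),
    class = "morph_spec"
  )
  af <- .band_area_fraction(spec)
  if (af <= 0 || af >= 0.6) {
    wm_stop("wm_config_error", sprintf(
      "band must cover a fraction of the wing in (0, 0.6), got %.3f", af
    ))
  }
  spec
}

#' Ground-truth colour specs of a morph
#'
#' The colour specs a perfectly informed analyst would use to extract this
#' morph's pattern: the band colours of the archetype at the generator's
#' extraction offset.
#'
#' @param spec A `morph_spec`.
#' @return List of [color_spec()]s.
#' @export
morph_color_specs <- function(spec) {
  pal <- spec$palette
  cols <- switch(spec$archetype,
    postman = list(red = pal$red),
    split = list(white = pal$white, red = pal$red),
    broken = list(yellow = pal$yellow)
  )
  mapply(function(nm, rgb) color_spec(nm, rgb, spec$extract_offset),
         names(cols), cols, SIMPLIFY = FALSE)
}

# band polygons (normalized coordinates) with their palette colour names
.band_polys_norm <- function(spec) {
  c0 <- spec$band_center + spec$band_offset
  w <- spec$band_width
  switch(spec$archetype,
    postman = list(list(
      poly = cbind(x = c(c0 - w / 2, c0 + w / 2, c0 + w / 2, c0 - w / 2),
                   y = c(-0.05, -0.05, 0.75, 0.75)),
      color = "red"
    )),
    split = list(
      list(poly = .ellipse_poly(c0, 0.22, w / 2, 0.11), color = "white"),
      list(poly = .ellipse_poly(c0, 0.46, w / 2, 0.11), color = "red")
    ),
    broken = list(
      list(poly = .ellipse_poly(c0, 0.16, w / 2, 0.075), color = "yellow"),
      list(poly = .ellipse_poly(c0, 0.33, w / 2, 0.075), color = "yellow"),
      list(poly = .ellipse_poly(c0, 0.50, w / 2, 0.075), color = "yellow")
    )
  )
}

# rasterize a polygon into an existing pixel mask, restricted to its
# bounding box for speed; pixel grid = one cell per pixel
.rasterize_px <- function(poly, h, w) {
  out <- matrix(0L, h, w)
  bx <- range(poly[, 1L]); by <- range(poly[, 2L])
  c0 <- max(1L, floor(bx[1L]) + 1L); c1 <- min(w, ceiling(bx[2L]))
  r0 <- max(1L, floor(by[1L]) + 1L); r1 <- min(h, ceiling(by[2L]))
  if (c0 > c1 || r0 > r1) return(out)
  sub <- rasterize_polygon(poly, r1 - r0 + 1L, c1 - c0 + 1L,
                           bounds = c(c0 - 1L, r0 - 1L, c1, r1),
                           check_simple = FALSE)
  out[r0:r1, c0:c1] <- sub
  out
}

# pixel-space geometry and masks of an (unjittered or warped) individual
.wing_masks_px <- function(outline_px, band_px, ko_px, h, w) {
  wing <- .rasterize_px(outline_px, h, w)
  band <- matrix(0L, h, w)
  per_color <- list()
  for (b in band_px) {
    m <- .rasterize_px(b$poly, h, w) & wing
    per_color[[length(per_color) + 1L]] <- list(mask = m, color = b$color)
    band <- band | m
  }
  if (!is.null(ko_px)) {
    m <- .rasterize_px(ko_px, h, w) & wing
    # knockout expansion renders in the primary band colour
    per_color[[length(per_color) + 1L]] <- list(mask = m, color = band_px[[1L]]$color)
    band <- band | m
  }
  list(wing = wing, band = band * 1L, per_color = per_color)
}

.render_image <- function(masks, palette, h, w, noise_sd) {
  img <- array(0, c(h, w, 3L))
  for (k in 1:3) img[, , k] <- palette$background[k]
  wing <- masks$wing == 1L
  for (k in 1:3) {
    plane <- img[, , k]
    plane[wing] <- palette$wing[k]
    img[, , k] <- plane
  }
  for (pc in masks$per_color) {
    sel <- pc$mask == 1L
    col <- palette[[pc$color]]
    for (k in 1:3) {
      plane <- img[, , k]
      plane[sel] <- col[k]
      img[, , k] <- plane
    }
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    img <- pmin(pmax(round(img), 0), 255)
  }
  img
}

# area of the band as a fraction of the wing, from the unjittered geometry
.band_area_fraction <- function(spec) {
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  s <- w  # isotropic normalized -> pixel scale
  outline <- .wing_outline_norm() * s
  bands <- lapply(.band_polys_norm(spec), function(b) {
    list(poly = b$poly * s, color = b$color)
  })
  ko <- if (!is.null(spec$ko_region)) spec$ko_region * s else NULL
  m <- .wing_masks_px(outline, bands, ko, h, w)
  sum(m$band) / sum(m$wing)
}

#' Generate a synthetic wing-image population
#'
#' Renders `n` individuals of one morph. The first individual is emitted
#' unjittered and serves as the common reference sample; every other
#' individual receives a smooth TPS warp (fitted from a 3 x 3 control grid
#' displaced by Gaussian noise) applied jointly to outline, band and
#' landmarks, then independent landmark digitization noise, pixel noise,
#' and (with probability `damage_rate`) a damage blotch recorded as an
#' exclusion polygon. Identical `(spec, n, seed)` give bit-identical
#' output.
#'
#' @param spec A `morph_spec`.
#' @param n Number of individuals (>= 0).
#' @param seed Integer seed fixing all randomness.
#' @param morph,species Labels written into the sample records.
#' @param genotype `"wild-type"` or `"KO"`.
#' @return Object of class `wing_population`: `samples` (each with `image`,
#'   `landmarks`, `exclusions`, `record`), `spec`, `seed` and `truth` — the
#'   generator's ground truth (reference outline and landmarks in pixel
#'   coordinates, the rendered reference band pixel mask, true relative
#'   band area, and for KO specs the true affected region and its area
#'   fraction of the wing).
#' @export
generate_population <- function(spec, n, seed, morph = spec$archetype,
                                species = "synthetic", genotype = "wild-type") {
  stopifnot(inherits(spec, "morph_spec"), n >= 0)
  set.seed(as.integer(seed))
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  s <- w
  outline0 <- .wing_outline_norm() * s
  lms0 <- .wing_landmarks_norm() * s
  bands0 <- lapply(.band_polys_norm(spec), function(b) {
    list(poly = b$poly * s, color = b$color)
  })
  ko0 <- if (!is.null(spec$ko_region)) spec$ko_region * s else NULL
  masks0 <- .wing_masks_px(outline0, bands0, ko0, h, w)
  ko_mask <- NULL
  ko_area_fraction <- NA_real_
  if (!is.null(ko0)) {
    base_band <- .wing_masks_px(outline0, bands0, NULL, h, w)$band
    ko_mask <- (masks0$band == 1L & base_band == 0L) * 1L
    ko_area_fraction <- sum(ko_mask) / sum(masks0$wing)
  }
  truth <- list(
    outline = outline0, landmarks = lms0,
    wing_mask = masks0$wing, band_mask = masks0$band,
    true_area = sum(masks0$band) / sum(masks0$wing),
    ko_mask = ko_mask, ko_area_fraction = ko_area_fraction
  )
  ctrl <- as.matrix(expand.grid(x = c(0, w / 2, w), y = c(0, h / 2, h)))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == 1L) {
      outline <- outline0; bands <- bands0; ko <- ko0; lms <- lms0
    } else {
      tgt <- ctrl + matrix(stats::rnorm(length(ctrl), 0, spec$warp_amplitude),
                           nrow(ctrl))
      warp <- fit_tps(ctrl, tgt)
      outline <- evaluate_tps(warp, outline0)
      bands <- lapply(bands0, function(b) {
        list(poly = evaluate_tps(warp, b$poly), color = b$color)
      })
      ko <- if (!is.null(ko0)) evaluate_tps(warp, ko0) else NULL
      lms <- evaluate_tps(warp, lms0) +
        matrix(stats::rnorm(length(lms0), 0, spec$jitter_sd), nrow(lms0))
    }
    masks <- if (i == 1L) masks0 else .wing_masks_px(outline, bands, ko, h, w)
    exclusions <- list()
    if (spec$damage_rate > 0 && stats::runif(1) < spec$damage_rate) {
      cx <- stats::runif(1, 0.25, 0.75) * s
      cy <- stats::runif(1, 0.20, 0.50) * s
      r <- stats::runif(1, 4, 10)
      blotch <- .ellipse_poly(cx, cy, r, r * stats::runif(1, 0.6, 1))
      dmg <- .rasterize_px(blotch, h, w) & masks$wing
      masks$per_color <- c(masks$per_color,
                           list(list(mask = dmg * 1L, color = "damage")))
      exclusions <- list(.ellipse_poly(cx, cy, r + 2, r + 2))
    }
    img <- .render_image(masks, spec$palette, h, w, spec$noise_sd)
    id <- sprintf("%s_%03d", morph, i)
    samples[[i]] <- list(
      image = img,
      landmarks = landmark_set(lms, image_id = id),
      exclusions = exclusions,
      record = data.frame(
        image_id = id, species = species, morph = morph,
        sex = c("male", "female")[(i %% 2L) + 1L],
        wing_side = c("left", "right")[(i %% 2L) + 1L],
        genotype = genotype, stringsAsFactors = FALSE
      )
    )
  }
  structure(
    list(samples = samples, spec = spec, seed = as.integer(seed), truth = truth),
    class = "wing_population"
  )
}

#' @export
print.wing_population <- function(x, ...) {
  cat(sprintf(
    "<wing_population> %d samples, archetype '%s', true band area %.3f of wing\n",
    length(x$samples), x$spec$archetype, x$truth$true_area
  ))
  invisible(x)
}

#' Reference frame built from a population's ground truth
#'
#' Uses the unjittered reference individual's landmarks and outline (the
#' study's "arbitrarily chosen reference sample", here known exactly).
#'
#' @param population A `wing_population`.
#' @param grid_shape Grid resolution (default `c(150, 150)`).
#' @param pixel If `TRUE`, build a pixel-matched frame: bounds equal to the
#'   image extent and one grid cell per pixel, so reference coordinates and
#'   reference pixels coincide exactly (useful when grid quantization must
#'   not blur areas).
#' @return A [reference_frame()].
#' @export
population_frame <- function(population, grid_shape = c(150L, 150L),
                             pixel = FALSE) {
  lms <- landmark_set(population$truth$landmarks, image_id = "reference")
  if (pixel) {
    h <- population$spec$image_size[1L]; w <- population$spec$image_size[2L]
    return(reference_frame(lms, population$truth$outline,
                           grid_shape = c(h, w), bounds = c(0, 0, w, h)))
  }
  reference_frame(lms, population$truth$outline, grid_shape = grid_shape)
}

#' Ground-truth band raster in the reference frame
#'
#' Samples the rendered reference individual's band pixel mask at the
#' frame's cell centers (nearest pixel). Because the reference individual
#' is unjittered, reference pixel space and frame coordinates coincide.
#'
#' @param population A `wing_population`.
#' @param frame A `reference_frame` (typically [population_frame()]).
#' @param which `"band"` (default) or `"ko"` for the KO-affected region.
#' @return Binary `pattern_raster`.
#' @export
truth_raster <- function(population, frame, which = c("band", "ko")) {
  which <- match.arg(which)
  mask <- if (which == "band") population$truth$band_mask else population$truth$ko_mask
  if (is.null(mask)) {
    wm_stop("wm_config_error", "population has no KO ground truth")
  }
  cc <- cell_centers(frame)
  g <- frame$grid_shape
  col <- floor(rep(cc$x, each = g[1L])) + 1L
  row <- floor(rep(cc$y, times = g[2L])) + 1L
  ok <- row >= 1L & row <= nrow(mask) & col >= 1L & col <= ncol(mask)
  v <- numeric(length(col))
  v[ok] <- mask[cbind(row[ok], col[ok])]
  pattern_raster(matrix(v, g[1L], g[2L]), "binary", frame)
}

# solve band_width so the band covers `target` fraction of the wing
.calibrate_band_width <- function(spec, target) {
  f <- function(width) {
    s2 <- spec; s2$band_width <- width
    .band_area_fraction(s2) - target
  }
  lo <- 0.02; hi <- 0.6
  if (f(lo) > 0 || f(hi) < 0) {
    wm_stop("wm_config_error", "target band area is out of the calibrable range")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
}

#' Generate a co-mimic pair of populations
#'
#' Population B is population A's morph with a positional band offset
#' and/or an area scaling. The band width of B is calibrated numerically so
#' that its true band area equals `area_scale` times A's — with
#' `area_scale = 1` this is the compensatory design in which two
#' populations match in pattern size while mismatching in position. The
#' paired truth records both base band masks, their exact differing region
#' (symmetric difference) and the true relative-area difference.
#'
#' @param spec_a `morph_spec` of population A.
#' @param n_a,n_b Population sizes (study populations ran 8-14 per morph).
#' @param seed Integer seed; population B uses `seed + 1`.
#' @param band_offset Positional shift of B's band, as a fraction of wing
#'   length.
#' @param area_scale True area of B's band relative to A's (default 1).
#' @return List with `pop_a`, `pop_b` (both `wing_population`) and `truth`
#'   (`area_a`, `area_b`, `area_difference`, `diff_mask` pixel matrix,
#'   `more_a_mask`, `more_b_mask`).
#' @export
generate_comimic_pair <- function(spec_a, n_a, n_b, seed, band_offset = 0,
                                  area_scale = 1) {
  spec_b <- spec_a
  spec_b$band_offset <- spec_a$band_offset + band_offset
  area_a <- .band_area_fraction(spec_a)
  spec_b$band_width <- .calibrate_band_width(spec_b, area_a * area_scale)
  pop_a <- generate_population(spec_a, n_a, seed, morph = "morph_A",
                               species = "species_A")
  pop_b <- generate_population(spec_b, n_b, seed + 1L, morph = "morph_B",
                               species = "species_B")
  band_a <- pop_a$truth$band_mask
  band_b <- pop_b$truth$band_mask
  truth <- list(
    area_a = pop_a$truth$true_area,
    area_b = pop_b$truth$true_area,
    area_difference = abs(pop_a$truth$true_area - pop_b$truth$true_area),
    diff_mask = (band_a != band_b) * 1L,
    more_a_mask = (band_a == 1L & band_b == 0L) * 1L,
    more_b_mask = (band_b == 1L & band_a == 0L) * 1L
  )
  list(pop_a = pop_a, pop_b = pop_b, truth = truth)
}

#' Generate paired wild-type and KO populations
#'
#' The KO population carries a proximal expansion of the band: a region
#' anterior-to-posterior strip proximal of the band edge, calibrated so the
#' truly affected (gained) area is `ko_area_fraction` of the wing —
#' emulating knockout phenotypes whose pattern expands into a known
#' territory.
#'
#' @param spec Wild-type `morph_spec`.
#' @param n_wt,n_ko Population sizes (the study's KO set was 10 wings of 5
#'   individuals).
#' @param seed Integer seed; the KO population uses `seed + 1`.
#' @param ko_area_fraction Target affected area as a fraction of the wing.
#' @return List with `wildtype`, `ko` (both `wing_population`); the KO
#'   population's `truth$ko_mask` / `truth$ko_area_fraction` hold the true
#'   affected region.
#' @export
generate_ko_pair <- function(spec, n_wt, n_ko, seed, ko_area_fraction = 0.1) {
  edge <- spec$band_center + spec$band_offset - spec$band_width / 2
  # compact square patch abutting the proximal band edge at mid-height,
  # clipped by the wing outline; side length calibrated to the target area
  patch <- function(len) {
    cbind(x = c(edge - len, edge + 0.005, edge + 0.005, edge - len),
          y = c(0.33 - len / 2, 0.33 - len / 2, 0.33 + len / 2, 0.33 + len / 2))
  }
  f <- function(len) {
    s2 <- spec
    s2$ko_region <- patch(len)
    .band_area_fraction_ko(s2) - ko_area_fraction
  }
  lo <- 0.01; hi <- 0.9
  if (f(hi) < 0) {
    wm_stop("wm_config_error", "ko_area_fraction is larger than the proximal wing region")
  }
  len <- stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
  spec_ko <- spec
  spec_ko$ko_region <- patch(len)
  list(
    wildtype = generate_population(spec, n_wt, seed, genotype = "wild-type"),
    ko = generate_population(spec_ko, n_ko, seed + 1L, genotype = "KO")
  )
}

# gained-area fraction of a spec carrying a ko_region
.band_area_fraction_ko <- function(spec) {
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  s <- w
  outline <- .wing_outline_norm() * s
  bands <- lapply(.band_polys_norm(spec), function(b) {
    list(poly = b$poly * s, color = b$color)
  })
  with_ko <- .wing_masks_px(outline, bands, spec$ko_region * s, h, w)
  base <- .wing_masks_px(outline, bands, NULL, h, w)
  sum(with_ko$band == 1L & base$band == 0L) / sum(with_ko$wing)
}

#' Write a population to disk as a drop-in dataset
#'
#' Emits the same formats the readers consume: PNG images, landmark CSVs,
#' exclusion-polygon CSVs and a sample manifest, ready for
#' [run_pipeline()].
#'
#' @param population A `wing_population`.
#' @param dir Output directory (created if needed).
#' @param manifest Write `manifest.csv` (default `TRUE`); set `FALSE` when
#'   combining several populations into one manifest.
#' @return Data frame of manifest rows, invisibly.
#' @export
write_population <- function(population, dir, manifest = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(population$samples, function(smp) {
    id <- smp$record$image_id
    img_path <- file.path(dir, paste0(id, ".png"))
    lm_path <- file.path(dir, paste0(id, "_landmarks.csv"))
    write_image(smp$image, img_path)
    write_landmarks(smp$landmarks, lm_path, dialect = "csv")
    mask_paths <- character()
    for (j in seq_along(smp$exclusions)) {
      mp <- file.path(dir, sprintf("%s_mask%d.csv", id, j))
      write_polygon(smp$exclusions[[j]], mp)
      mask_paths <- c(mask_paths, mp)
    }
    cbind(smp$record, data.frame(
      image = img_path, landmarks = lm_path,
      masks = paste(mask_paths, collapse = ";"), stringsAsFactors = FALSE
    ))
  })
  out <- do.call(rbind, rows)
  if (manifest && !is.null(out)) {
    utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  invisible(out)
}
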