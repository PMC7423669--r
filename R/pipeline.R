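# Configuration-driven orchestration: extraction -> registration ->
# aggregation -> PCA -> statistics -> KO overlay, with a reproducible
# report bundle (CSV/PNG artefacts plus a machine-readable run log).

#' Extract and align one sample into the reference frame
#'
#' Convenience composition of the per-sample pipeline: colour extraction,
#' exclusion masking, TPS warp into the reference frame.
#'
#' @param image RGB array (0..255).
#' @param landmarks `landmark_set` of the sample.
#' @param frame The `reference_frame`.
#' @param specs Colour spec(s) for this sample's morph.
#' @param exclusions List of exclusion polygons (possibly empty).
#' @param metric Colour metric for [extract_color()].
#' @return Binary `pattern_raster`.
#' @export
extract_and_align <- function(image, landmarks, frame, specs,
                              exclusions = list(),
                              metric = c("chebyshev", "euclidean")) {
  mask <- extract_color(image, specs, metric = match.arg(metric))
  mask <- apply_exclusions(mask, exclusions)
  warp_mask_to_reference(mask, landmarks, frame)
}

#' Extract and align every sample of a synthetic population
#'
#' @param population A `wing_population`.
#' @param frame A `reference_frame` (default [population_frame()]).
#' @param specs Colour specs (default the population's ground-truth specs).
#' @return List of binary `pattern_raster`s, named by sample id.
#' @export
align_population <- function(population, frame = population_frame(population),
                             specs = morph_color_specs(population$spec)) {
  out <- lapply(population$samples, function(smp) {
    extract_and_align(smp$image, smp$landmarks, frame, specs, smp$exclusions)
  })
  names(out) <- vapply(population$samples, function(s) s$record$image_id, "")
  out
}

.cfg_get <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) wm_stop("wm_config_error", sprintf("config key '%s' is required", key))
  default
}

.parse_color_specs <- function(lst) {
  lapply(lst, function(morph_specs) {
    lapply(morph_specs, function(s) {
      color_spec(s$name, unlist(s$rgb), s$offset)
    })
  })
}

.stats_row <- function(comparison, res) {
  data.frame(
    comparison = comparison, test = res$test_name,
    statistic = res$statistic,
    df1 = res$df[1L], df2 = if (length(res$df) > 1L) res$df[2L] else NA_real_,
    p = res$p_value, stringsAsFactors = FALSE
  )
}

#' Run the full colour-pattern analysis from a configuration file
#'
#' Executes the declared analysis end-to-end and writes a versioned output
#' directory holding frequency maps, difference maps, mismatch and
#' statistics tables, PCA scores and loadings, KO consensus contours and a
#' machine-readable run log (config checksum, seed, per-stage counts).
#' Re-running with identical inputs and configuration is bit-identical for
#' the deterministic stages.
#'
#' Configuration keys: `manifest`, `reference_id`, `outline` (reference
#' wing-outline polygon file), `output_dir`, `seed`; optional `grid_shape`
#' (rows, cols; default 150 x 150), `landmark_dialect` (`csv`/`tps`),
#' `color_metric`, `color_specs` (per-morph lists of
#' `{name, rgb, offset}`), `comparisons` (list of
#' `{type: comimic, group_a, group_b}` or `{type: ko, wildtype, ko}`
#' entries, groups named by morph), `pca` (`enabled`, `group_by`,
#' `select`), `stats` (`p_adjust`: `none` or `holm`).
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list.
#' @return Invisibly, a list with the frame, per-morph rasters, frequency
#'   maps, comparison results, PCA model and the run-log list.
#' @export
run_pipeline <- function(config) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    if (!file.exists(config)) {
      wm_stop("wm_io_error", sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  seed <- .cfg_get(config, "seed", 1L)
  set.seed(as.integer(seed))
  out_dir <- .cfg_get(config, "output_dir", required = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = seed, started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stages = list())
  if (!is.null(config_path)) {
    log$config_md5 <- unname(tools::md5sum(config_path))
  }

  manifest <- read_manifest(.cfg_get(config, "manifest", required = TRUE))
  dialect <- .cfg_get(config, "landmark_dialect", "csv")
  metric <- .cfg_get(config, "color_metric", "chebyshev")
  grid_shape <- unlist(.cfg_get(config, "grid_shape", c(150L, 150L)))
  color_specs <- .parse_color_specs(.cfg_get(config, "color_specs", list()))

  ref_id <- .cfg_get(config, "reference_id", required = TRUE)
  ref_row <- manifest[manifest$image_id == ref_id, , drop = FALSE]
  if (nrow(ref_row) != 1L) {
    wm_stop("wm_config_error",
            sprintf("reference sample '%s' not found in manifest", ref_id))
  }
  ref_lms <- read_landmarks(ref_row$landmarks, dialect = dialect,
                            image_id = ref_id)
  outline <- read_polygon(.cfg_get(config, "outline", required = TRUE))
  frame <- reference_frame(ref_lms, outline, grid_shape = grid_shape)

  # per-sample extraction + alignment
  rasters <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    specs <- color_specs[[row$morph]]
    if (is.null(specs)) {
      wm_stop("wm_config_error",
              sprintf("manifest row %d (sample '%s'): no colour specs for morph '%s'",
                      i, row$image_id, row$morph))
    }
    raster <- tryCatch({
      img <- read_image(row$image)
      lms <- read_landmarks(row$landmarks, dialect = dialect,
                            image_height = nrow(img), image_id = row$image_id)
      excl <- list()
      if (nzchar(row$masks)) {
        excl <- lapply(strsplit(row$masks, ";")[[1L]], read_polygon)
      }
      extract_and_align(img, lms, frame, specs, excl, metric = metric)
    }, wingmatch_error = function(e) {
      wm_stop("wm_io_error",
              sprintf("sample '%s' (manifest row %d): %s",
                      row$image_id, i, conditionMessage(e)))
    })
    rasters[[row$image_id]] <- raster
  }
  log$stages$aligned_samples <- length(rasters)

  by_morph <- split(names(rasters), manifest$morph)
  freq_maps <- lapply(by_morph, function(ids) frequency_map(rasters[ids]))
  for (m in names(freq_maps)) {
    write_raster_csv(freq_maps[[m]], file.path(out_dir, sprintf("freq_%s.csv", m)))
    write_raster_png(freq_maps[[m]], file.path(out_dir, sprintf("freq_%s.png", m)))
  }
  log$stages$frequency_maps <- length(freq_maps)

  stats_rows <- list()
  mismatch_rows <- list()
  comparisons <- .cfg_get(config, "comparisons", list())
  ko_rows <- list()
  for (cmp in comparisons) {
    if (identical(cmp$type, "comimic")) {
      ga <- cmp$group_a; gb <- cmp$group_b
      for (g in c(ga, gb)) {
        if (is.null(by_morph[[g]])) {
          wm_stop("wm_config_error", sprintf("comparison names unknown morph '%s'", g))
        }
      }
      ms <- mismatch_summary(rasters[by_morph[[ga]]], rasters[by_morph[[gb]]])
      dm <- difference_map(ms$frequency_a, ms$frequency_b)
      tag <- sprintf("%s_vs_%s", ga, gb)
      write_raster_csv(dm, file.path(out_dir, sprintf("diff_%s.csv", tag)))
      write_raster_png(dm, file.path(out_dir, sprintf("diff_%s.png", tag)))
      mismatch_rows[[tag]] <- data.frame(
        comparison = tag,
        absolute_mismatch = ms$absolute_mismatch,
        relative_area_difference = ms$relative_area_difference,
        mean_area_a = mean(ms$per_sample_areas_a),
        mean_area_b = mean(ms$per_sample_areas_b),
        stringsAsFactors = FALSE
      )
      stats_rows[[paste0(tag, "_abs")]] <- .stats_row(
        tag, one_sample_t(c(ms$per_sample_mismatch_a, ms$per_sample_mismatch_b), 0)
      )
      stats_rows[[paste0(tag, "_rel")]] <- .stats_row(
        tag, two_sample_t(ms$per_sample_areas_a, ms$per_sample_areas_b)
      )
    } else if (identical(cmp$type, "ko")) {
      wt_ids <- by_morph[[cmp$wildtype]]
      ko_ids <- by_morph[[cmp$ko]]
      if (is.null(wt_ids) || is.null(ko_ids)) {
        wm_stop("wm_config_error", "ko comparison names unknown morph")
      }
      wt_cons <- ko_consensus(rasters[wt_ids], frame = frame)
      ko_sum <- ko_consensus(rasters[ko_ids], frame = frame)
      area <- ko_affected_area(rasters[ko_ids], wt_cons$consensus)
      tag <- sprintf("%s_KO_vs_%s", cmp$ko, cmp$wildtype)
      contour_df <- do.call(rbind, lapply(seq_along(ko_sum$contours), function(k) {
        data.frame(contour = k, x = ko_sum$contours[[k]]$x,
                   y = ko_sum$contours[[k]]$y)
      }))
      if (!is.null(contour_df)) {
        utils::write.csv(contour_df,
                         file.path(out_dir, sprintf("contours_%s.csv", tag)),
                         row.names = FALSE)
      }
      write_raster_csv(ko_sum$consensus,
                       file.path(out_dir, sprintf("consensus_%s.csv", tag)))
      ko_rows[[tag]] <- data.frame(
        comparison = tag, n_wings = length(ko_ids),
        affected_mean_pct = area$mean, affected_sd_pct = area$sd,
        gain_mean_pct = area$gain$mean, loss_mean_pct = area$loss$mean,
        stringsAsFactors = FALSE
      )
    } else {
      wm_stop("wm_config_error",
              sprintf("unknown comparison type '%s'", cmp$type))
    }
  }
  log$stages$comparisons <- length(comparisons)

  # PCA + group statistics
  pca_cfg <- .cfg_get(config, "pca", list(enabled = length(rasters) >= 3))
  pca_model <- NULL
  if (isTRUE(pca_cfg$enabled %||% TRUE) && length(rasters) >= 3L) {
    pca_model <- fit_raster_pca(rasters, ids = names(rasters))
    axes <- select_axes(pca_model,
                        method = pca_cfg$select %||% "broken-stick",
                        threshold = pca_cfg$threshold %||% 0.9,
                        k = pca_cfg$k)
    scores_df <- data.frame(
      image_id = rownames(pca_model$scores),
      manifest[match(rownames(pca_model$scores), manifest$image_id),
               c("species", "morph", "sex", "genotype")],
      pca_model$scores, row.names = NULL
    )
    utils::write.csv(scores_df, file.path(out_dir, "pca_scores.csv"),
                     row.names = FALSE)
    for (a in utils::head(seq_len(ncol(pca_model$scores)), 4L)) {
      write_raster_png(loading_raster(pca_model, a),
                       file.path(out_dir, sprintf("pca_loading_%d.png", a)))
    }
    group_by <- pca_cfg$group_by %||% "species"
    labels <- manifest[[group_by]][match(rownames(pca_model$scores),
                                         manifest$image_id)]
    if (length(axes) && length(unique(labels)) >= 2L &&
        min(table(labels)) >= 3L) {
      sc <- pca_model$scores[, axes, drop = FALSE]
      stats_rows[["manova"]] <- .stats_row(
        sprintf("%s (PC %s)", group_by, paste(axes, collapse = ",")),
        manova_scores(sc, labels)
      )
      rep <- lda_classify(sc, labels)
      utils::write.csv(
        data.frame(group = names(rep$posterior_pct),
                   mean_posterior_pct = as.numeric(rep$posterior_pct)),
        file.path(out_dir, "lda_posterior.csv"), row.names = FALSE
      )
    }
    log$stages$pca_axes_retained <- length(axes)
  }

  stats_df <- do.call(rbind, unname(stats_rows))
  if (!is.null(stats_df)) {
    adjust <- (.cfg_get(config, "stats", list())$p_adjust) %||% "none"
    if (!identical(adjust, "none")) {
      stats_df$p_adjusted <- stats::p.adjust(stats_df$p, method = adjust)
    }
    utils::write.csv(stats_df, file.path(out_dir, "statistics.csv"),
                     row.names = FALSE)
  }
  mismatch_df <- do.call(rbind, unname(mismatch_rows))
  if (!is.null(mismatch_df)) {
    utils::write.csv(mismatch_df, file.path(out_dir, "mismatch.csv"),
                     row.names = FALSE)
  }
  ko_df <- do.call(rbind, unname(ko_rows))
  if (!is.null(ko_df)) {
    utils::write.csv(ko_df, file.path(out_dir, "ko_area.csv"), row.names = FALSE)
  }

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    frame = frame, rasters = rasters, frequency_maps = freq_maps,
    mismatch = mismatch_df, statistics = stats_df, ko = ko_df,
    pca = pca_model, log = log
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
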