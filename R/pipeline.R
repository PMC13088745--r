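#' Pipeline configuration
#'
#' Collects every tunable of the three analysis stages plus paths and
#' the global seed, so a run is fully described by one object; the
#' configuration is serialized into the output directory for
#' provenance.  Library defaults equal CLI defaults.
#'
#' @param images_dir directory of channel-image TIFFs (with sidecars),
#'   or `NULL` to skip the width stage.
#' @param masks_dir directory of label-mask TIFFs, or `NULL` to skip
#'   morphometry.
#' @param cohort_csv longitudinal width table, or `NULL` to build the
#'   cohort from the measured images.
#' @param out_dir output directory (created if needed).
#' @param spacing,margin,correction_factor,min_run_px width-stage
#'   parameters (um, um, unitless, px).
#' @param min_area_um2 morphometry minimum region area, um^2.
#' @param kw_descriptor descriptor column tested by Kruskal-Wallis.
#' @param kw_by grouping column for the Kruskal-Wallis comparison.
#' @param ci_level confidence level of the mixed-model intervals.
#' @param p_adjust Dunn multiplicity adjustment.
#' @param pixel_size_um optional pixel-size override applied to every
#'   input lacking sidecar calibration.
#' @param seed global seed (stochastic stages only).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(images_dir = NULL, masks_dir = NULL,
                            cohort_csv = NULL, out_dir = "chipmorph-out",
                            spacing = 25, margin = 100,
                            correction_factor = 1, min_run_px = 3L,
                            min_area_um2 = 200,
                            kw_descriptor = "aspect_ratio",
                            kw_by = "day",
                            ci_level = 0.95, p_adjust = "bonferroni",
                            pixel_size_um = NULL, seed = 1L) {
  stopifnot(spacing > 0, margin >= 0, correction_factor > 0,
            min_run_px >= 1, min_area_um2 >= 0,
            ci_level > 0, ci_level < 1)
  structure(list(
    images_dir = images_dir, masks_dir = masks_dir,
    cohort_csv = cohort_csv, out_dir = out_dir,
    spacing = spacing, margin = margin,
    correction_factor = correction_factor,
    min_run_px = as.integer(min_run_px),
    min_area_um2 = min_area_um2,
    kw_descriptor = kw_descriptor, kw_by = kw_by,
    ci_level = ci_level, p_adjust = p_adjust,
    pixel_size_um = pixel_size_um, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Measures every image, computes morphometry on every mask, then runs
#' the longitudinal statistics, writing CSV/JSON outputs and a run
#' manifest (configuration snapshot, input checksums, per-stage record
#' counts, warnings) into `config$out_dir`.  A rerun with identical
#' configuration and inputs reproduces identical outputs.  Any stage
#' failure aborts with the stage name and the offending input.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  counts <- list()
  checksums <- list()

  note <- function(...) message(sprintf(...))

  # stage 1: width measurement
  chip_widths <- NULL
  if (!is.null(config$images_dir)) {
    paths <- sort(list.files(config$images_dir, pattern = "\\.tiff?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(paths) == 0) {
      stop(sprintf("stage measure-width: no TIFF images in %s",
                   config$images_dir), call. = FALSE)
    }
    checksums$images <- as.list(tools::md5sum(paths))
    note("measure-width: %d images", length(paths))
    measurements <- lapply(paths, function(p) {
      withCallingHandlers(
        tryCatch(
          measure_image(read_channel_image(p,
                                           pixel_size = config$pixel_size_um),
                        spacing = config$spacing, margin = config$margin,
                        correction_factor = config$correction_factor,
                        min_run_px = config$min_run_px),
          error = function(e) {
            stop(sprintf("stage measure-width failed on %s: %s",
                         p, conditionMessage(e)), call. = FALSE)
          }),
        warning = function(w) {
          warnings_log <<- c(warnings_log,
                             sprintf("measure-width %s: %s", basename(p),
                                     conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
    })
    profiles <- purrr::map_dfr(measurements, tidy)
    per_image <- purrr::map_dfr(measurements, glance)
    readr::write_csv(profiles, file.path(config$out_dir, "profiles.csv"))
    readr::write_csv(per_image, file.path(config$out_dir, "per_image.csv"))
    chip_widths <- summarize_measurements(measurements)
    readr::write_csv(chip_widths, file.path(config$out_dir, "per_chip.csv"))
    counts$images <- length(paths)
    counts$profiles <- nrow(profiles)
    counts$chips_measured <- nrow(chip_widths)
  }

  # stage 2: morphometry
  cells <- NULL
  if (!is.null(config$masks_dir)) {
    paths <- sort(list.files(config$masks_dir, pattern = "\\.tiff?$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(paths) == 0) {
      stop(sprintf("stage morphometry: no TIFF masks in %s",
                   config$masks_dir), call. = FALSE)
    }
    checksums$masks <- as.list(tools::md5sum(paths))
    note("morphometry: %d masks", length(paths))
    cells <- purrr::map_dfr(paths, function(p) {
      tryCatch({
        mask <- read_label_mask(p, pixel_size = config$pixel_size_um)
        mask |>
          remove_border_labels() |>
          shape_descriptors() |>
          filter_by_area(min_area = config$min_area_um2)
      }, error = function(e) {
        stop(sprintf("stage morphometry failed on %s: %s",
                     p, conditionMessage(e)), call. = FALSE)
      })
    })
    readr::write_csv(cells, file.path(config$out_dir, "cells.csv"))
    summary_tab <- summarize_morphology(cells)
    readr::write_csv(summary_tab,
                     file.path(config$out_dir, "morphology_summary.csv"))
    counts$masks <- length(paths)
    counts$cells <- nrow(cells)
  }

  # stage 3: longitudinal statistics
  cohort <- NULL
  if (!is.null(config$cohort_csv)) {
    checksums$cohort <- as.list(tools::md5sum(config$cohort_csv))
    cohort <- read_cohort(config$cohort_csv)
  } else if (!is.null(chip_widths) &&
             !anyNA(chip_widths$group) && !anyNA(chip_widths$day)) {
    cohort <- chip_widths[c("chip_id", "group", "day", "width_um")]
  }
  if (!is.null(cohort)) {
    note("stats: %d chip-day records", nrow(cohort))
    counts$cohort_rows <- nrow(cohort)
    readr::write_csv(describe_widths(cohort),
                     file.path(config$out_dir, "width_summary.csv"))
    if (length(unique(cohort$group)) >= 2) {
      fit <- tryCatch(fit_lmm(cohort, ci_level = config$ci_level),
                      error = function(e) {
                        stop(sprintf("stage stats-lmm failed: %s",
                                     conditionMessage(e)), call. = FALSE)
                      })
      div <- ci_divergence_day(fit)
      readr::write_csv(tidy(fit),
                       file.path(config$out_dir, "lmm_predictions.csv"))
      jsonlite::write_json(list(
        method = fit$method, ci_level = fit$ci_level,
        predictions = tidy(fit), covariance = fit$covariance,
        first_divergence_day = div$first_divergence_day,
        per_day_overlap = div$per_day
      ), file.path(config$out_dir, "lmm_fit.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
      counts$lmm_cells <- nrow(tidy(fit))
    }
  }
  if (!is.null(cells) && nrow(cells) > 0 &&
      length(unique(cells[[config$kw_by]])) >= 2) {
    kw <- kruskal_dunn(cells, config$kw_descriptor, config$kw_by,
                       p_adjust = config$p_adjust)
    readr::write_csv(tidy(kw), file.path(config$out_dir, "kw_dunn.csv"))
    counts$kw_comparisons <- nrow(tidy(kw))
  }

  manifest <- list(
    package = "chipmorph",
    version = as.character(packageVersion("chipmorph")),
    config = unclass(config),
    input_checksums = checksums,
    counts = counts,
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yml"))
  invisible(manifest)
}
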