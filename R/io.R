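#' Write a channel image as TIFF with a YAML sidecar
#'
#' The fluorescence (and optional brightfield) raster is stored as a
#' 32-bit float TIFF, one page per channel; because TIFF float storage
#' is defined on \[0, 1\], intensities are affinely rescaled into that
#' range when needed and the transform is recorded in the sidecar so
#' reading reconstructs the original values.  Pixel size and metadata
#' travel in a `<path>.yml` sidecar — the TIFF alone is deliberately not
#' trusted for calibration.
#'
#' @param image a [channel_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_channel_image <- function(image, path) {
  stopifnot(inherits(image, "channel_image"))
  pages <- list(fluorescence = image$fluorescence)
  if (!is.null(image$brightfield)) pages$brightfield <- image$brightfield
  rng <- range(unlist(lapply(pages, range)))
  if (rng[1] < 0 || rng[2] > 1) {
    offset <- rng[1]
    scale <- max(rng[2] - rng[1], .Machine$double.eps)
  } else {
    offset <- 0
    scale <- 1
  }
  stored <- lapply(pages, function(m) (m - offset) / scale)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(unname(stored), path, bits.per.sample = 32,
                  reduce = FALSE)
  yaml::write_yaml(list(
    pixel_size_um = image$pixel_size,
    chip_id = image$chip_id,
    day = as_scalar(image$day),
    group = image$group,
    channels = names(pages),
    intensity_offset = offset,
    intensity_scale = scale
  ), sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yml")

as_scalar <- function(x) if (length(x) == 1 && is.na(x)) NA else x

#' Read a channel image written by [write_channel_image()]
#'
#' Pixel size resolves as: explicit `pixel_size` argument, else sidecar
#' value; a missing pixel size is an error, never a silent default.
#'
#' @param path TIFF path.
#' @param pixel_size optional um/px override.
#' @param channels optional character vector naming the role of each
#'   TIFF page (overrides the sidecar), e.g.
#'   `c("fluorescence", "brightfield")`.
#' @return A [channel_image()].
#' @export
read_channel_image <- function(path, pixel_size = NULL, channels = NULL) {
  if (!file.exists(path)) stop(sprintf("no such image: %s", path),
                               call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else list()
  if (is.null(channels)) channels <- meta$channels
  if (is.null(channels)) channels <- c("fluorescence", "brightfield")[seq_along(pages)]
  if (length(channels) != length(pages) || !"fluorescence" %in% channels) {
    stop("cannot resolve channel roles: supply `channels` naming each TIFF page.",
         call. = FALSE)
  }
  names(pages) <- channels
  ps <- pixel_size %||% meta$pixel_size_um
  if (is.null(ps)) {
    stop(sprintf(
      "pixel size missing for %s: none in the sidecar and no override supplied.",
      path), call. = FALSE)
  }
  offset <- meta$intensity_offset %||% 0
  scale <- meta$intensity_scale %||% 1
  pages <- lapply(pages, function(m) m * scale + offset)
  channel_image(
    fluorescence = pages$fluorescence,
    brightfield = pages$brightfield,
    pixel_size = ps,
    chip_id = meta$chip_id %||% NA_character_,
    day = as_int_or_na(meta$day),
    group = meta$group %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_int_or_na <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) NA_integer_ else as.integer(x)
}

#' Write / read an integer label mask as 16-bit TIFF with YAML sidecar
#'
#' Labels (up to 65535) are stored exactly in the 16-bit payload; pixel
#' size, location, day and chip id travel in the sidecar.
#'
#' @param mask a [label_mask()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535) stop("more than 65535 labels.", call. = FALSE)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16)
  yaml::write_yaml(list(
    pixel_size_um = mask$pixel_size,
    location = mask$location,
    day = as_scalar(mask$day),
    chip_id = mask$chip_id,
    kind = "label_mask"
  ), sidecar_path(path))
  invisible(path)
}

#' @rdname write_label_mask
#' @param pixel_size optional um/px override.
#' @export
read_label_mask <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("no such mask: %s", path),
                               call. = FALSE)
  raw <- tiff::readTIFF(path)
  meta <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else list()
  ps <- pixel_size %||% meta$pixel_size_um
  if (is.null(ps)) {
    stop(sprintf("pixel size missing for %s.", path), call. = FALSE)
  }
  lab <- matrix(as.integer(round(raw * 65535)), nrow(raw), ncol(raw))
  label_mask(lab, pixel_size = ps,
             location = meta$location %||% NA_character_,
             day = as_int_or_na(meta$day),
             chip_id = meta$chip_id %||% NA_character_)
}

#' Write / read a longitudinal cohort table as CSV
#'
#' Columns: `chip_id`, `group`, `day`, `width_um`.
#'
#' @param cohort cohort tibble.
#' @param path CSV path.
#' @return `path` invisibly (write) or the cohort tibble (read).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(validate_cohort(cohort), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  validate_cohort(readr::read_csv(
    path, col_types = readr::cols(
      chip_id = readr::col_character(),
      group = readr::col_character(),
      day = readr::col_integer(),
      width_um = readr::col_double())))
}
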