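#' Configure a synthetic lumen scene
#'
#' Describes a low-magnification view of a microfluidic channel holding a
#' fluorescent endothelial lumen: channel walls at fixed pixel columns, a
#' bright lumen band of prescribed width between them, and optional blur,
#' illumination gradient and additive Gaussian noise.  Defaults reproduce
#' the package's reference chip geometry: a 1300 um wide channel (400 px
#' wall separation at 3.25 um/px) imaged over a 1200 x 600 px field of
#' view (about two thirds of a 6 mm channel).
#'
#' @param image_height_px,image_width_px raster dimensions in pixels; the
#'   channel runs along rows.
#' @param pixel_size isotropic pixel size, um/px.
#' @param wall_left_x,wall_right_x pixel columns of the inner wall edges;
#'   the channel interior spans `wall_left_x..wall_right_x`.
#' @param lumen_width_um lumen width in um: a scalar (constant width), a
#'   vector with one value per image row, or a function of the row
#'   position in um along the channel axis.  Defaults to the full wall
#'   separation (a wall-attached lumen).
#' @param lumen_center_offset_um lateral offset of the band centre from
#'   the channel midline, um.
#' @param intensity_lumen,intensity_background band and background
#'   intensities (arbitrary units); lumen must exceed background.
#' @param noise_sd additive Gaussian noise standard deviation, same units.
#' @param blur_sigma Gaussian blur sigma in px (0 = no blur).
#' @param illumination_gradient linear multiplicative intensity gradient
#'   across the image width, as a total fraction (0.1 = +-5% at the
#'   edges).
#' @param wall_band_px thickness of the dark wall bands drawn on the
#'   brightfield raster, px.
#' @param seed integer seed driving the noise.
#'
#' @return A `scene_config` list.
#' @seealso [generate_lumen_scene()]
#' @export
scene_config <- function(image_height_px = 1200L,
                         image_width_px = 600L,
                         pixel_size = 3.25,
                         wall_left_x = 101L,
                         wall_right_x = 501L,
                         lumen_width_um = NULL,
                         lumen_center_offset_um = 0,
                         intensity_lumen = 0.8,
                         intensity_background = 0.1,
                         noise_sd = 0,
                         blur_sigma = 0,
                         illumination_gradient = 0,
                         wall_band_px = 8L,
                         seed = 1L) {
  cfg <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size = pixel_size,
    wall_left_x = as.integer(wall_left_x),
    wall_right_x = as.integer(wall_right_x),
    lumen_width_um = lumen_width_um,
    lumen_center_offset_um = lumen_center_offset_um,
    intensity_lumen = intensity_lumen,
    intensity_background = intensity_background,
    noise_sd = noise_sd,
    blur_sigma = blur_sigma,
    illumination_gradient = illumination_gradient,
    wall_band_px = as.integer(wall_band_px),
    seed = as.integer(seed)
  )
  if (is.null(cfg$lumen_width_um)) {
    cfg$lumen_width_um <- (cfg$wall_right_x - cfg$wall_left_x) * cfg$pixel_size
  }
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(
    cfg$image_height_px >= 1, cfg$image_width_px >= 2,
    cfg$pixel_size > 0, cfg$noise_sd >= 0, cfg$blur_sigma >= 0,
    cfg$wall_band_px >= 1
  )
  if (cfg$wall_left_x >= cfg$wall_right_x) {
    stop("`wall_left_x` must be strictly less than `wall_right_x`.", call. = FALSE)
  }
  if (cfg$wall_right_x > cfg$image_width_px || cfg$wall_left_x < 1) {
    stop("wall positions must lie within the image width.", call. = FALSE)
  }
  if (cfg$intensity_lumen <= cfg$intensity_background) {
    stop("`intensity_lumen` must exceed `intensity_background`.", call. = FALSE)
  }
  invisible(cfg)
}

# Resolve the per-row lumen width specification to a numeric vector (um).
resolve_width_profile <- function(cfg) {
  n <- cfg$image_height_px
  row_um <- (seq_len(n) - 1) * cfg$pixel_size
  w <- cfg$lumen_width_um
  if (is.function(w)) w <- w(row_um)
  if (length(w) == 1L) w <- rep(w, n)
  if (length(w) != n) {
    stop("`lumen_width_um` must be scalar, length image_height_px, or a function.",
         call. = FALSE)
  }
  sep_um <- (cfg$wall_right_x - cfg$wall_left_x) * cfg$pixel_size
  if (any(w > sep_um + 1e-9)) {
    stop(sprintf(
      "geometry error: requested lumen width (max %.2f um) exceeds the wall separation (%.2f um).",
      max(w), sep_um), call. = FALSE)
  }
  if (any(w < 0)) stop("lumen widths must be non-negative.", call. = FALSE)
  w
}

#' Render a synthetic fluorescence + brightfield channel scene
#'
#' Draws the lumen as a bright band between the channel walls on the
#' fluorescence raster, then applies (in order) Gaussian blur, a linear
#' illumination gradient across the width, and seeded additive Gaussian
#' noise.  The brightfield raster shows dark wall bands ending at the
#' wall columns.  The exact per-row band edges are recorded as ground
#' truth before any degradation is applied.
#'
#' The band on row r occupies pixel columns `left_px..right_px`
#' inclusive, with `right_px - left_px = round(width_um / pixel_size)`,
#' so the recorded true width `(right_px - left_px) * pixel_size` is the
#' requested width rounded to a whole number of pixels.
#'
#' @param config a [scene_config()].
#' @param chip_id,day,group metadata attached to the returned image.
#'
#' @return A list with elements
#'   * `image`: a `channel_image` (fluorescence + brightfield matrices,
#'     pixel size, metadata);
#'   * `truth`: a tibble with one row per image row
#'     (`row`, `row_um`, `left_px`, `right_px`, `width_um`) plus
#'     attributes; and
#'   * `true_mean_width`: mean of the per-row true widths, um.
#' @examples
#' sc <- generate_lumen_scene(scene_config(image_height_px = 200,
#'                                         image_width_px = 300,
#'                                         wall_left_x = 51, wall_right_x = 251,
#'                                         lumen_width_um = 500))
#' sc$true_mean_width
#' @export
generate_lumen_scene <- function(config = scene_config(),
                                 chip_id = "chip01", day = NA_integer_,
                                 group = NA_character_) {
  validate_scene_config(config)
  n <- config$image_height_px
  m <- config$image_width_px
  ps <- config$pixel_size
  w_um <- resolve_width_profile(config)
  w_px <- round(w_um / ps)

  center_px <- (config$wall_left_x + config$wall_right_x) / 2 +
    config$lumen_center_offset_um / ps
  left_px <- round(center_px - w_px / 2)
  right_px <- left_px + w_px
  # keep the band inside the channel even after centre rounding
  shift <- pmax(config$wall_left_x - left_px, 0) -
    pmax(right_px - config$wall_right_x, 0)
  left_px <- left_px + shift
  right_px <- right_px + shift

  fluor <- matrix(config$intensity_background, n, m)
  for (r in seq_len(n)) {
    if (w_px[r] >= 0) fluor[r, left_px[r]:right_px[r]] <- config$intensity_lumen
  }

  truth <- tibble::tibble(
    row = seq_len(n),
    row_um = (seq_len(n) - 1) * ps,
    left_px = as.integer(left_px),
    right_px = as.integer(right_px),
    width_um = (right_px - left_px) * ps
  )

  if (config$blur_sigma > 0) {
    fluor <- EBImage::gblur(fluor, sigma = config$blur_sigma)
  }
  if (config$illumination_gradient != 0) {
    g <- config$illumination_gradient
    fac <- 1 + g * ((seq_len(m) - 1) / (m - 1) - 0.5)
    fluor <- sweep(fluor, 2, fac, `*`)
  }
  if (config$noise_sd > 0) {
    fluor <- fluor + withr::with_seed(
      config$seed, matrix(rnorm(n * m, sd = config$noise_sd), n, m))
  }

  bf <- matrix(0.85, n, m)
  lw <- max(1L, config$wall_left_x - config$wall_band_px + 1L):config$wall_left_x
  rw <- config$wall_right_x:min(m, config$wall_right_x + config$wall_band_px - 1L)
  bf[, lw] <- 0.15
  bf[, rw] <- 0.15

  image <- channel_image(fluorescence = fluor, brightfield = bf,
                         pixel_size = ps, chip_id = chip_id,
                         day = day, group = group)
  list(image = image,
       truth = truth,
       true_mean_width = mean(truth$width_um),
       wall_left_x = config$wall_left_x,
       wall_right_x = config$wall_right_x)
}

#' Calibrated single- or dual-channel chip image
#'
#' @param fluorescence numeric matrix of fluorescence intensities.
#' @param brightfield optional numeric matrix, same dimensions.
#' @param pixel_size um/px, > 0.
#' @param chip_id,day,group metadata.
#' @return A `channel_image` object.
#' @export
channel_image <- function(fluorescence, brightfield = NULL, pixel_size,
                          chip_id = NA_character_, day = NA_integer_,
                          group = NA_character_) {
  stopifnot(is.matrix(fluorescence), is.numeric(fluorescence), pixel_size > 0)
  if (!is.null(brightfield) &&
      !identical(dim(brightfield), dim(fluorescence))) {
    stop("brightfield and fluorescence rasters must share dimensions.",
         call. = FALSE)
  }
  structure(list(fluorescence = fluorescence, brightfield = brightfield,
                 pixel_size = pixel_size, chip_id = chip_id,
                 day = day, group = group),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$fluorescence)
  cat(sprintf("<channel_image> %d x %d px @ %.3g um/px", d[1], d[2],
              x$pixel_size))
  if (!is.null(x$brightfield)) cat(" (+ brightfield)")
  cat(sprintf("\n  chip: %s  day: %s  group: %s\n",
              x$chip_id, x$day, x$group))
  invisible(x)
}
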