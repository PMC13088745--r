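#' Otsu threshold of an intensity histogram
#'
#' Computes the histogram cut maximizing the between-class variance
#' (equivalently, minimizing the within-class variance) and returns the
#' corresponding bin boundary as an intensity threshold.  Accepts either
#' a raw intensity raster/vector, which is binned into `n_bins` equal
#' bins over its range, or a precomputed histogram (a list or
#' `histogram` object with `counts` and `breaks`).  Bin midpoints
#' represent the intensity of each bin; ties are broken toward the lower
#' cut.
#'
#' @param x numeric vector/matrix of intensities, or a histogram with
#'   elements `counts` (length K) and `breaks` (length K + 1).
#' @param n_bins number of histogram bins when `x` is raw intensities.
#' @return A single threshold intensity: pixels strictly above it are
#'   foreground.
#' @examples
#' otsu_threshold(c(rep(10, 50), rep(200, 50)))
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  h <- as_intensity_histogram(x, n_bins)
  counts <- h$counts
  breaks <- h$breaks
  if (sum(counts > 0) < 2) {
    stop("degenerate histogram: fewer than 2 non-empty bins (constant image?).",
         call. = FALSE)
  }
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[length(m0)]
  # candidate cuts after bin k, k = 1..K-1
  k <- seq_len(length(p) - 1)
  w0k <- w0[k]; m0k <- m0[k]
  valid <- w0k > 0 & w0k < 1
  sb2 <- rep(-Inf, length(k))
  sb2[valid] <- (mt * w0k[valid] - m0k[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  best <- which.max(sb2)
  breaks[best + 1]
}

as_intensity_histogram <- function(x, n_bins) {
  if (is.list(x) && !is.null(x$counts) && !is.null(x$breaks)) {
    stopifnot(length(x$breaks) == length(x$counts) + 1)
    return(list(counts = as.numeric(x$counts), breaks = as.numeric(x$breaks)))
  }
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no finite intensities.", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    # single occupied bin; let otsu_threshold() report the degeneracy
    return(list(counts = length(v), breaks = rng + c(0, 1)))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  list(counts = counts, breaks = breaks)
}

#' Otsu threshold scaled by an empirical correction factor
#'
#' The lumen edge detector thresholds each cross-channel profile at the
#' image-wide Otsu threshold multiplied by a correction factor; the
#' factor compensates for the bias of a global histogram cut toward the
#' bright lumen interior.  Its value is an acquisition-specific tuning
#' knob with default 1 (plain Otsu).
#'
#' @inheritParams otsu_threshold
#' @param correction_factor strictly positive multiplier.
#' @return Threshold intensity (`otsu_threshold(x) * correction_factor`).
#' @export
corrected_threshold <- function(x, correction_factor = 1, n_bins = 256L) {
  if (!is.numeric(correction_factor) || length(correction_factor) != 1 ||
      correction_factor <= 0) {
    stop("`correction_factor` must be a single positive number.", call. = FALSE)
  }
  otsu_threshold(x, n_bins) * correction_factor
}

#' Cross-channel profile grid
#'
#' Lays an evenly spaced grid of cross-channel intensity profiles along
#' the channel axis (image rows), excluding a margin at each end where
#' the lumen edges may leave the field of view.  Grid positions are
#' `margin, margin + spacing, ...` up to `extent - margin`, with
#' `extent = (n_rows - 1) * pixel_size`; each profile is the pixel row
#' nearest its grid position.
#'
#' @param x a `channel_image`, a fluorescence matrix, or an integer row
#'   count.
#' @param pixel_size um/px (taken from `x` when it is a `channel_image`).
#' @param spacing grid spacing, um (> 0).
#' @param margin excluded extent at each end, um (>= 0).
#' @return Tibble with columns `position_um` (grid position) and `row`
#'   (nearest pixel row).
#' @examples
#' nrow(extract_profiles(741, pixel_size = 2.5, spacing = 25, margin = 0))
#' @export
extract_profiles <- function(x, pixel_size = NULL, spacing = 25,
                             margin = 100) {
  if (inherits(x, "channel_image")) {
    n_rows <- nrow(x$fluorescence)
    pixel_size <- x$pixel_size
  } else if (is.matrix(x)) {
    n_rows <- nrow(x)
  } else {
    n_rows <- as.integer(x)
  }
  stopifnot(!is.null(pixel_size), pixel_size > 0, spacing > 0, margin >= 0)
  extent <- (n_rows - 1) * pixel_size
  if (2 * margin >= extent && margin > 0) {
    stop("no profiles: twice the margin exceeds the image extent.",
         call. = FALSE)
  }
  pos <- seq(margin, extent - margin, by = spacing)
  if (length(pos) == 0) {
    stop("no profiles: empty grid after margin exclusion.", call. = FALSE)
  }
  tibble::tibble(position_um = pos,
                 row = pmin(pmax(round(pos / pixel_size) + 1L, 1L), n_rows))
}

#' Detect lumen edges on one intensity profile
#'
#' The lumen spans from the start of the first supra-threshold run of at
#' least `min_run_px` pixels to the end of the last such run.  A profile
#' with no qualifying run is flagged invalid (not an error); invalid
#' profiles are excluded from averaging and counted.  The minimum run
#' length rejects isolated hot pixels.
#'
#' @param intensities numeric vector (one image row across the channel).
#' @param threshold intensity above which a pixel counts as lumen.
#' @param min_run_px minimum supra-threshold run length, px (>= 1).
#' @return A list with `left_px`, `right_px` (pixel columns; `NA` when
#'   invalid) and `valid`.
#' @export
detect_lumen_edges <- function(intensities, threshold, min_run_px = 3L) {
  stopifnot(length(intensities) > 0, min_run_px >= 1)
  r <- rle(as.vector(intensities) > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= min_run_px)
  if (length(qual) == 0) {
    return(list(left_px = NA_integer_, right_px = NA_integer_, valid = FALSE))
  }
  list(left_px = starts[qual[1]],
       right_px = ends[qual[length(qual)]],
       valid = TRUE)
}

#' Projected width from an edge pair
#'
#' Profiles are perpendicular to the channel axis, so the Euclidean
#' distance between the two edge points reduces to their in-profile
#' separation: `(right_px - left_px) * pixel_size`.
#'
#' @param left_px,right_px edge pixel columns, `left_px <= right_px`.
#' @param pixel_size um/px.
#' @return Width in um.
#' @examples
#' projected_width(10, 410, 3.25)
#' @export
projected_width <- function(left_px, right_px, pixel_size) {
  stopifnot(pixel_size > 0)
  if (any(right_px < left_px)) {
    stop("reversed edges: `left_px` must not exceed `right_px`.",
         call. = FALSE)
  }
  (right_px - left_px) * pixel_size
}

#' Wall calibration for a chip image
#'
#' Records the pixel column of the leftmost channel wall and how it was
#' obtained.  Supplying it manually mirrors the original protocol of
#' clicking the wall on the brightfield image; [detect_wall()] offers an
#' automated proposal.
#'
#' @param wall_left_x pixel column of the left wall.
#' @param channel_axis axis along which the channel runs (only `"rows"`
#'   is currently supported; rotate the image otherwise).
#' @param source `"manual"` or `"automatic"`.
#' @return A `wall_calibration` object.
#' @export
wall_calibration <- function(wall_left_x, channel_axis = "rows",
                             source = c("manual", "automatic")) {
  source <- match.arg(source)
  stopifnot(channel_axis == "rows", wall_left_x >= 1)
  structure(list(wall_left_x = as.integer(wall_left_x),
                 channel_axis = channel_axis, source = source),
            class = "wall_calibration")
}

#' Propose a wall calibration from a brightfield image
#'
#' Scans the column-mean brightfield profile for the leftmost strong
#' dark-to-light transition (walls image dark) and proposes that column
#' as the left wall.  A manually supplied calibration always takes
#' precedence and is returned verbatim.
#'
#' @param x a `channel_image` with a brightfield raster, or a brightfield
#'   matrix.
#' @param manual optional [wall_calibration()] returned unchanged.
#' @return A [wall_calibration()] with `source = "automatic"` (or the
#'   manual one).
#' @export
detect_wall <- function(x, manual = NULL) {
  if (!is.null(manual)) {
    stopifnot(inherits(manual, "wall_calibration"))
    return(manual)
  }
  bf <- if (inherits(x, "channel_image")) x$brightfield else x
  if (is.null(bf)) {
    stop("no brightfield raster: supply a manual wall calibration.",
         call. = FALSE)
  }
  cm <- colMeans(bf)
  rng <- range(cm)
  if (diff(rng) < 1e-8 * max(abs(rng), 1)) {
    stop("flat brightfield: no wall transition found; manual calibration required.",
         call. = FALSE)
  }
  dark <- cm < mean(rng)
  trans <- which(dark[-length(dark)] & !dark[-1])
  if (length(trans) == 0) {
    stop("no dark-to-light transition found; manual calibration required.",
         call. = FALSE)
  }
  wall_calibration(trans[1], source = "automatic")
}

#' Measure the projected lumen width of one chip image
#'
#' End-to-end width quantification for a single image: one Otsu
#' threshold on the fluorescence raster scaled by the empirical
#' correction factor, an evenly spaced profile grid with end margins,
#' per-profile edge detection with a minimum run length, per-profile
#' projected widths, and their mean over valid profiles.
#'
#' @param image a [channel_image()].
#' @param spacing profile spacing along the channel axis, um.
#' @param margin excluded extent at each end of the channel axis, um.
#' @param correction_factor multiplier on the Otsu threshold (> 0).
#' @param min_run_px minimum supra-threshold run length, px.
#' @param calibration optional [wall_calibration()]; recorded in the
#'   result (the row-aligned grid needs no rotation when the channel
#'   runs along rows).
#' @param n_bins histogram bins for the Otsu threshold.
#' @return A `width_measurement` object: per-profile tibble (audit
#'   trail), threshold used, mean width over valid profiles, and counts.
#'   `tidy()` returns the per-profile table, `glance()` the one-row
#'   summary.
#' @examples
#' sc <- generate_lumen_scene(scene_config(image_height_px = 400,
#'                                         image_width_px = 300,
#'                                         wall_left_x = 51, wall_right_x = 251))
#' glance(measure_image(sc$image))
#' @export
measure_image <- function(image, spacing = 25, margin = 100,
                          correction_factor = 1, min_run_px = 3L,
                          calibration = NULL, n_bins = 256L) {
  stopifnot(inherits(image, "channel_image"))
  thr <- corrected_threshold(image$fluorescence, correction_factor, n_bins)
  grid <- extract_profiles(image, spacing = spacing, margin = margin)
  edges <- purrr::map(grid$row, function(r) {
    detect_lumen_edges(image$fluorescence[r, ], thr, min_run_px)
  })
  profiles <- tibble::tibble(
    chip_id = image$chip_id, day = image$day, group = image$group,
    position_um = grid$position_um, row = grid$row,
    left_px = purrr::map_int(edges, "left_px"),
    right_px = purrr::map_int(edges, "right_px"),
    valid = purrr::map_lgl(edges, "valid")
  )
  profiles$width_um <- ifelse(
    profiles$valid,
    (profiles$right_px - profiles$left_px) * image$pixel_size,
    NA_real_)
  n_valid <- sum(profiles$valid)
  if (n_valid == 0) {
    stop(sprintf("no valid profile on image '%s' (day %s): nothing to average.",
                 image$chip_id, image$day), call. = FALSE)
  }
  structure(list(
    profiles = profiles,
    threshold = thr,
    correction_factor = correction_factor,
    spacing = spacing, margin = margin, min_run_px = as.integer(min_run_px),
    pixel_size = image$pixel_size,
    calibration = calibration,
    mean_width = mean(profiles$width_um[profiles$valid]),
    n_valid_profiles = n_valid,
    n_profiles = nrow(profiles),
    chip_id = image$chip_id, day = image$day, group = image$group
  ), class = "width_measurement")
}

#' @export
print.width_measurement <- function(x, ...) {
  cat(sprintf(
    "<width_measurement> chip %s day %s: mean width %.2f um (%d/%d valid profiles, threshold %.4g)\n",
    x$chip_id, x$day, x$mean_width, x$n_valid_profiles, x$n_profiles,
    x$threshold))
  invisible(x)
}

#' @rdname measure_image
#' @param x a `width_measurement`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.width_measurement <- function(x, ...) x$profiles

#' @rdname measure_image
#' @exportS3Method generics::glance
glance.width_measurement <- function(x, ...) {
  tibble::tibble(chip_id = x$chip_id, day = x$day, group = x$group,
                 mean_width_um = x$mean_width,
                 n_valid_profiles = x$n_valid_profiles,
                 n_profiles = x$n_profiles, threshold = x$threshold,
                 correction_factor = x$correction_factor)
}

#' Per-chip width table from a set of measurements
#'
#' Aggregates image-level measurements to one row per chip and day; when
#' a chip contributes several images on a day their mean widths are
#' averaged with equal weight.
#'
#' @param measurements a list of `width_measurement` objects.
#' @return Tibble with `chip_id`, `group`, `day`, `width_um`, `n_images`.
#' @export
summarize_measurements <- function(measurements) {
  purrr::map_dfr(measurements, glance) |>
    dplyr::group_by(.data$chip_id, .data$group, .data$day) |>
    dplyr::summarise(width_um = mean(.data$mean_width_um),
                     n_images = dplyr::n(), .groups = "drop")
}
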