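#' Configure a synthetic cell-label mask
#'
#' Parameters for drawing non-overlapping elliptical (or rectangular)
#' cells into an integer label raster, emulating a segmented endothelial
#' monolayer.  Cell area, elongation and orientation are drawn per cell
#' from the stated distributions; placement is by rejection sampling with
#' a retry cap, and every pair of placed cells is separated by at least
#' `min_gap_px` background pixels (Chebyshev distance).
#'
#' @param n_cells number of cells to attempt to place (>= 0).
#' @param area_distribution `c(mean, sd)` of cell area, um^2 (truncated
#'   at a one-pixel minimum).
#' @param aspect_ratio_distribution `c(mean, sd)` of the major/minor
#'   elongation (truncated at 1).
#' @param orientation_distribution either `NULL` (uniform on \[0, 180))
#'   or `c(mean, sd)` degrees, wrapped into \[0, 180).
#' @param shape_family `"ellipse"` or `"rectangle"`.
#' @param min_gap_px minimum background gap between distinct labels, px.
#' @param image_height_px,image_width_px raster dimensions.
#' @param pixel_size um/px.
#' @param max_tries placement attempts per cell before giving up.
#' @param seed integer seed.
#' @return A `mask_config` list.
#' @seealso [generate_cell_mask()]
#' @export
mask_config <- function(n_cells = 50L,
                        area_distribution = c(600, 150),
                        aspect_ratio_distribution = c(2, 0.5),
                        orientation_distribution = NULL,
                        shape_family = c("ellipse", "rectangle"),
                        min_gap_px = 2L,
                        image_height_px = 512L,
                        image_width_px = 512L,
                        pixel_size = 1,
                        max_tries = 200L,
                        seed = 1L) {
  shape_family <- match.arg(shape_family)
  stopifnot(n_cells >= 0, min_gap_px >= 1, pixel_size > 0,
            length(area_distribution) == 2, area_distribution[1] > 0,
            length(aspect_ratio_distribution) == 2,
            aspect_ratio_distribution[1] >= 1,
            max_tries >= 1)
  structure(list(
    n_cells = as.integer(n_cells),
    area_distribution = area_distribution,
    aspect_ratio_distribution = aspect_ratio_distribution,
    orientation_distribution = orientation_distribution,
    shape_family = shape_family,
    min_gap_px = as.integer(min_gap_px),
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size = pixel_size,
    max_tries = as.integer(max_tries),
    seed = as.integer(seed)
  ), class = "mask_config")
}

# Pixel centres covered by an ellipse/rectangle centred at (cr, cc) px
# with semi-axes a >= b px, rotated by theta degrees from the image
# horizontal (counter-clockwise with y pointing up, i.e. against rows).
rasterize_shape <- function(cr, cc, a, b, theta_deg, family) {
  rad <- theta_deg * pi / 180
  ext <- ceiling(max(a, b)) + 1L
  rows <- floor(cr - ext):ceiling(cr + ext)
  cols <- floor(cc - ext):ceiling(cc + ext)
  g <- expand.grid(row = rows, col = cols)
  dx <- g$col - cc
  dy <- -(g$row - cr)          # image rows grow downward
  xr <- dx * cos(rad) + dy * sin(rad)
  yr <- -dx * sin(rad) + dy * cos(rad)
  inside <- if (family == "ellipse") {
    (xr / a)^2 + (yr / b)^2 <= 1
  } else {
    abs(xr) <= a & abs(yr) <= b
  }
  g[inside, , drop = FALSE]
}

#' Generate a labelled cell mask with ground-truth shape parameters
#'
#' Places `n_cells` shapes by rejection sampling: each candidate is
#' redrawn until it fits inside the image and its footprint, dilated by
#' `min_gap_px`, touches no previously placed label.  If a cell cannot be
#' placed within `max_tries` attempts a warning is raised and the mask is
#' returned with fewer cells (never silently truncated).
#'
#' @param config a [mask_config()].
#' @param chip_id,day,location metadata attached to the returned mask.
#' @return A list with `mask` (a [label_mask()]) and `truth` (a tibble of
#'   the drawn parameters per placed cell: `label_id`, `area_um2`,
#'   `aspect_ratio`, `orientation_deg`, `center_row_px`, `center_col_px`,
#'   `n_px`).
#' @examples
#' mk <- generate_cell_mask(mask_config(n_cells = 5, seed = 7))
#' mk$truth
#' @export
generate_cell_mask <- function(config = mask_config(),
                               chip_id = "chip01", day = NA_integer_,
                               location = NA_character_) {
  nr <- config$image_height_px
  nc <- config$image_width_px
  ps <- config$pixel_size
  gap <- config$min_gap_px
  labels <- matrix(0L, nr, nc)
  # occupancy dilated by `gap`: TRUE where a new cell pixel may NOT go
  blocked <- matrix(FALSE, nr, nc)
  off <- expand.grid(dr = -gap:gap, dc = -gap:gap)

  truth <- vector("list", config$n_cells)
  placed <- 0L

  withr::with_seed(config$seed, {
    for (i in seq_len(config$n_cells)) {
      ok <- FALSE
      for (try in seq_len(config$max_tries)) {
        area <- max(rnorm(1, config$area_distribution[1],
                          config$area_distribution[2]), ps^2)
        ar <- max(rnorm(1, config$aspect_ratio_distribution[1],
                        config$aspect_ratio_distribution[2]), 1)
        theta <- if (is.null(config$orientation_distribution)) {
          runif(1, 0, 180)
        } else {
          rnorm(1, config$orientation_distribution[1],
                config$orientation_distribution[2]) %% 180
        }
        area_px <- area / ps^2
        if (config$shape_family == "ellipse") {
          a <- sqrt(area_px * ar / pi); b <- a / ar
        } else {                       # full area = (2a)(2b)
          a <- sqrt(area_px * ar) / 2; b <- a / ar
        }
        if (nr - a <= 1 + a || nc - a <= 1 + a) next  # cell larger than image
        cr <- runif(1, 1 + a, nr - a)
        cc <- runif(1, 1 + a, nc - a)
        px <- rasterize_shape(cr, cc, a, b, theta, config$shape_family)
        if (nrow(px) == 0) next
        if (min(px$row) < 1 || max(px$row) > nr ||
            min(px$col) < 1 || max(px$col) > nc) next
        idx <- cbind(px$row, px$col)
        if (any(blocked[idx])) next
        placed <- placed + 1L
        labels[idx] <- placed
        # block the dilated footprint for later cells
        for (k in seq_len(nrow(off))) {
          rr <- px$row + off$dr[k]; cc2 <- px$col + off$dc[k]
          keep <- rr >= 1 & rr <= nr & cc2 >= 1 & cc2 <= nc
          blocked[cbind(rr[keep], cc2[keep])] <- TRUE
        }
        truth[[placed]] <- tibble::tibble(
          label_id = placed, area_um2 = area, aspect_ratio = ar,
          orientation_deg = theta, center_row_px = cr, center_col_px = cc,
          n_px = nrow(px))
        ok <- TRUE
        break
      }
      if (!ok) {
        warning(sprintf(
          "placed only %d of %d cells after %d tries each; returning a partial mask.",
          placed, config$n_cells, config$max_tries), call. = FALSE)
        break
      }
    }
  })

  truth <- if (placed > 0) dplyr::bind_rows(truth[seq_len(placed)]) else
    tibble::tibble(label_id = integer(), area_um2 = numeric(),
                   aspect_ratio = numeric(), orientation_deg = numeric(),
                   center_row_px = numeric(), center_col_px = numeric(),
                   n_px = integer())
  list(mask = label_mask(labels, pixel_size = ps, chip_id = chip_id,
                         day = day, location = location),
       truth = truth)
}

#' Integer-labelled segmentation mask
#'
#' @param labels integer matrix, 0 = background, positive ids = cells.
#' @param pixel_size um/px, > 0.
#' @param location `"floor"`, `"membrane"` or `NA`.
#' @param day,chip_id metadata.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, pixel_size, location = NA_character_,
                       day = NA_integer_, chip_id = NA_character_) {
  stopifnot(is.matrix(labels), pixel_size > 0)
  if (any(labels < 0)) stop("labels must be non-negative.", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size = pixel_size,
                 location = location, day = day, chip_id = chip_id),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_mask> %d x %d px @ %.3g um/px, %d labels\n",
              d[1], d[2], x$pixel_size,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}
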