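#' Remove labels touching the image border
#'
#' Cells clipped by the field of view bias every shape descriptor, so any
#' label with at least one pixel on the outermost rows or columns is set
#' to background.  Remaining label ids are preserved; the operation is
#' idempotent.
#'
#' @param mask a [label_mask()] or integer label matrix.
#' @return Same type as the input, border labels blanked.
#' @export
remove_border_labels <- function(mask) {
  lab <- if (inherits(mask, "label_mask")) mask$labels else mask
  nr <- nrow(lab); nc <- ncol(lab)
  border_ids <- setdiff(unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc])), 0L)
  if (length(border_ids) > 0) lab[lab %in% border_ids] <- 0L
  if (inherits(mask, "label_mask")) {
    mask$labels <- lab
    mask
  } else {
    lab
  }
}

# Boundary pixels of one label: pixels with at least one 4-neighbour
# outside the label (or on the image edge).  Their hull over pixel
# corners equals the hull over all pixel corners of the label.
boundary_pixels <- function(lab, id) {
  idx <- which(lab == id, arr.ind = TRUE)
  nr <- nrow(lab); nc <- ncol(lab)
  inside <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- logical(length(r))
    out[ok] <- lab[cbind(r[ok], c[ok])] == id
    out
  }
  r <- idx[, 1]; c <- idx[, 2]
  interior <- inside(r - 1, c) & inside(r + 1, c) &
    inside(r, c - 1) & inside(r, c + 1)
  idx[!interior, , drop = FALSE]
}

# Corner points (x = col, y = -row, px units) of a set of pixels.
pixel_corners <- function(px) {
  r <- rep(px[, 1], each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  c <- rep(px[, 2], each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  unique(cbind(x = c, y = -r))
}

# Maximum caliper (Feret) diameter and the angle of the maximising
# chord, from a set of boundary corner points.  Convex hull first, then
# exact max pairwise distance over the hull vertices.
feret_from_points <- function(pts) {
  if (nrow(pts) > 2) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  n <- nrow(pts)
  if (n == 1) return(list(diameter = 0, angle = 0))
  d2 <- as.matrix(stats::dist(pts))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  p <- pts[ij[1], ]; q <- pts[ij[2], ]
  ang <- (atan2(q[2] - p[2], q[1] - p[1]) * 180 / pi) %% 180
  list(diameter = sqrt(max(d2)), angle = unname(ang))
}

#' Shape descriptors of every label in a mask
#'
#' Per label: area as pixel count times the pixel area; aspect ratio as
#' the major/minor axis ratio of the ellipse matching the region's
#' second central moments (pixels treated as unit squares, adding 1/12
#' to each moment, so a single pixel has aspect ratio exactly 1 and an
#' axis-aligned w x h rectangle exactly w/h); Feret diameter as the
#' maximum caliper distance over the label's boundary-pixel corner
#' points (convex hull, then exact pairwise maximum); and Feret angle as
#' the orientation of the maximising chord measured counter-clockwise
#' from the image horizontal axis, in \[0, 180).  A single-pixel label
#' has Feret diameter equal to the pixel diagonal.
#'
#' @param mask a [label_mask()] or integer label matrix (then supply
#'   `pixel_size`).
#' @param pixel_size um/px; overrides the mask's own value if given.
#' @return Tibble with one row per label: `label_id`, `area_um2`,
#'   `aspect_ratio`, `feret_um`, `feret_angle_deg`, `centroid_row_px`,
#'   `centroid_col_px`, plus `chip_id`, `day`, `location` metadata when
#'   the input is a `label_mask`.
#' @examples
#' m <- matrix(0L, 20, 50); m[6:15, 6:45] <- 1L
#' shape_descriptors(m, pixel_size = 1)
#' @export
shape_descriptors <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "label_mask")) {
    lab <- mask$labels
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
    meta <- mask[c("chip_id", "day", "location")]
  } else {
    lab <- mask
    meta <- NULL
  }
  stopifnot(!is.null(pixel_size), pixel_size > 0)
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  res <- purrr::map_dfr(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    n_px <- nrow(px)
    # second central moments with the per-pixel uniform-square term
    mu_r <- mean(px[, 1]); mu_c <- mean(px[, 2])
    vrr <- mean((px[, 1] - mu_r)^2) + 1 / 12
    vcc <- mean((px[, 2] - mu_c)^2) + 1 / 12
    vrc <- mean((px[, 1] - mu_r) * (px[, 2] - mu_c))
    tr <- vrr + vcc
    det <- vrr * vcc - vrc^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc
    l2 <- max(tr / 2 - disc, .Machine$double.eps)
    fer <- feret_from_points(pixel_corners(boundary_pixels(lab, id)))
    tibble::tibble(
      label_id = id,
      area_um2 = n_px * pixel_size^2,
      aspect_ratio = sqrt(l1 / l2),
      feret_um = fer$diameter * pixel_size,
      feret_angle_deg = fer$angle,
      centroid_row_px = mu_r,
      centroid_col_px = mu_c
    )
  })
  if (length(ids) == 0) {
    res <- tibble::tibble(label_id = integer(), area_um2 = numeric(),
                          aspect_ratio = numeric(), feret_um = numeric(),
                          feret_angle_deg = numeric(),
                          centroid_row_px = numeric(),
                          centroid_col_px = numeric())
  }
  if (!is.null(meta)) {
    res$chip_id <- meta$chip_id
    res$day <- meta$day
    res$location <- meta$location
  }
  res
}

#' Minimum-area filter for cell shapes
#'
#' Removes regions strictly smaller than `min_area` (a region of exactly
#' `min_area` is retained); such regions typically correspond to gaps
#' between cells or segmentation artifacts rather than cells.  Order is
#' preserved.
#'
#' @param shapes tibble from [shape_descriptors()] (needs `area_um2`).
#' @param min_area threshold in um^2 (default 200).
#' @return Filtered tibble.
#' @export
filter_by_area <- function(shapes, min_area = 200) {
  stopifnot(min_area >= 0, "area_um2" %in% names(shapes))
  dplyr::filter(shapes, .data$area_um2 >= min_area)
}

#' Group summaries of shape descriptors
#'
#' Median and quartiles (linear-interpolation quantiles, R type 7) of
#' each descriptor per group, with group sizes.  Empty groups that are
#' present as factor levels report `n = 0` and no statistics.
#'
#' @param shapes tibble with descriptor columns and grouping columns.
#' @param by character vector of grouping columns present in `shapes`
#'   (default day and location).
#' @param descriptors descriptor columns to summarise.
#' @return Long tibble: grouping columns, `descriptor`, `n`, `median`,
#'   `q25`, `q75`.
#' @export
summarize_morphology <- function(shapes, by = c("day", "location"),
                                 descriptors = c("area_um2", "aspect_ratio",
                                                 "feret_um",
                                                 "feret_angle_deg")) {
  by <- intersect(by, names(shapes))
  descriptors <- intersect(descriptors, names(shapes))
  stopifnot(length(by) > 0, length(descriptors) > 0)
  shapes |>
    tidyr::pivot_longer(dplyr::all_of(descriptors),
                        names_to = "descriptor", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "descriptor")))) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      median = if (n > 0) median(.data$value, na.rm = TRUE) else NA_real_,
      q25 = if (n > 0)
        unname(quantile(.data$value, 0.25, na.rm = TRUE, type = 7)) else NA_real_,
      q75 = if (n > 0)
        unname(quantile(.data$value, 0.75, na.rm = TRUE, type = 7)) else NA_real_,
      .groups = "drop")
}
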