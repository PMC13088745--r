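make_mask <- function(nr, nc, setter) {
  lab <- matrix(0L, nr, nc)
  setter(lab)
}

test_that("border labels are removed and removal is idempotent", {
  lab <- matrix(0L, 30, 30)
  lab[1:5, 10:14] <- 1L        # touches row 1
  lab[10:14, 10:14] <- 2L      # interior
  lab[25:30, 2:6] <- 3L        # touches last row
  out <- remove_border_labels(lab)
  expect_identical(sort(unique(as.vector(out))), c(0L, 2L))
  expect_identical(remove_border_labels(out), out)

  all_border <- matrix(1L, 8, 8)
  expect_true(all(remove_border_labels(all_border) == 0L))

  # label_mask wrapper preserved
  m <- label_mask(lab, pixel_size = 2, location = "floor")
  out2 <- remove_border_labels(m)
  expect_s3_class(out2, "label_mask")
  expect_identical(out2$labels, out)
})

test_that("rectangle descriptors match area and the brute-force Feret oracle", {
  lab <- matrix(0L, 60, 60)
  lab[11:20, 11:50] <- 1L      # 10 x 40 px axis-aligned rectangle
  sh <- shape_descriptors(lab, pixel_size = 1)
  expect_equal(sh$area_um2, 400)
  expect_equal(sh$aspect_ratio, 4, tolerance = 1e-9)
  expect_equal(sh$feret_um, brute_force_feret(lab, 1L), tolerance = 1e-12)
  # the maximal chord of a rectangle is its corner-to-corner diagonal
  expect_equal(sh$feret_um, sqrt(40^2 + 10^2), tolerance = 1e-9)
})

test_that("Feret diameter equals exhaustive pairwise search on random blobs", {
  set.seed(33)
  for (i in 1:12) {
    mk <- generate_cell_mask(mask_config(
      n_cells = 3, seed = i, image_height_px = 150, image_width_px = 150,
      area_distribution = c(300, 120),
      aspect_ratio_distribution = c(2.5, 1)))
    sh <- shape_descriptors(mk$mask)
    for (id in sh$label_id) {
      expect_equal(sh$feret_um[sh$label_id == id],
                   brute_force_feret(mk$mask$labels, id),
                   tolerance = 1e-12)
    }
  }
})

test_that("a rasterized disc is round and its Feret spans the diameter", {
  lab <- matrix(0L, 60, 60)
  ctr <- 30.5
  for (r in 1:60) for (c in 1:60) {
    if ((r - ctr)^2 + (c - ctr)^2 <= 20^2) lab[r, c] <- 1L
  }
  sh <- shape_descriptors(lab, pixel_size = 1)
  expect_lt(abs(sh$aspect_ratio - 1), 0.05)
  expect_lt(abs(sh$feret_um - 40), 2)
})

test_that("orientation of an elongated shape is recovered within tolerance", {
  # thin rectangles: the max-Feret chord (diagonal) is within 2 deg of
  # the long axis, so the recovered angle tracks the construction angle
  for (theta in c(0, 30, 60, 117, 150)) {
    px <- chipmorph:::rasterize_shape(75, 75, 60, 1.5, theta, "rectangle")
    lab <- matrix(0L, 150, 150)
    lab[cbind(px$row, px$col)] <- 1L
    sh <- shape_descriptors(lab, pixel_size = 1)
    delta <- abs(sh$feret_angle_deg - theta) %% 180
    expect_lt(min(delta, 180 - delta), 2.5)
  }
})

test_that("rotating a shape shifts its Feret angle by the rotation", {
  # ellipses: the max-Feret chord is the major axis, so the angle shift
  # tracks the rotation up to rasterization error
  base <- 20
  for (theta in c(25, 70, 140)) {
    px0 <- chipmorph:::rasterize_shape(75, 75, 50, 12, base, "ellipse")
    px1 <- chipmorph:::rasterize_shape(75, 75, 50, 12, base + theta,
                                       "ellipse")
    mk <- function(px) {
      lab <- matrix(0L, 150, 150); lab[cbind(px$row, px$col)] <- 1L; lab
    }
    a0 <- shape_descriptors(mk(px0), pixel_size = 1)$feret_angle_deg
    a1 <- shape_descriptors(mk(px1), pixel_size = 1)$feret_angle_deg
    delta <- abs((a1 - a0) %% 180 - theta %% 180)
    expect_lt(min(delta, 180 - delta), 2)
  }
})

test_that("doubling pixel size doubles Feret and quadruples area exactly", {
  mk <- generate_cell_mask(mask_config(n_cells = 4, seed = 8,
                                       image_height_px = 120,
                                       image_width_px = 120))
  s1 <- shape_descriptors(mk$mask$labels, pixel_size = 1)
  s2 <- shape_descriptors(mk$mask$labels, pixel_size = 2)
  expect_equal(s2$area_um2, 4 * s1$area_um2)
  expect_equal(s2$feret_um, 2 * s1$feret_um)
  expect_equal(s2$aspect_ratio, s1$aspect_ratio)
})

test_that("single-pixel labels use the documented conventions", {
  lab <- matrix(0L, 10, 10); lab[5, 5] <- 1L
  sh <- shape_descriptors(lab, pixel_size = 3)
  expect_equal(sh$area_um2, 9)
  expect_equal(sh$aspect_ratio, 1)
  expect_equal(sh$feret_um, 3 * sqrt(2))
})

test_that("the minimum-area filter removes strictly smaller regions only", {
  shapes <- tibble::tibble(label_id = 1:3,
                           area_um2 = c(100, 200, 350))
  kept <- filter_by_area(shapes, min_area = 200)
  expect_identical(kept$label_id, 2:3)       # exactly 200 is retained
  expect_true(all(kept$area_um2 >= 200))
  expect_identical(nrow(filter_by_area(shapes[0, ], 200)), 0L)
  expect_lte(nrow(filter_by_area(shapes, 200)), nrow(shapes))
})

test_that("morphology summaries use interpolated quartiles and report n", {
  shapes <- tibble::tibble(
    day = rep(c(3L, 10L), c(5, 4)),
    location = "floor",
    aspect_ratio = c(1, 2, 3, 4, 5, 2, 2, 2, 2))
  s <- summarize_morphology(shapes, by = "day",
                            descriptors = "aspect_ratio")
  d3 <- s[s$day == 3, ]
  expect_identical(d3$n, 5L)
  expect_equal(d3$median, 3)
  expect_equal(d3$q25, 2)
  d10 <- s[s$day == 10, ]
  expect_equal(d10$median, 2)
  expect_equal(d10$q75 - d10$q25, 0)         # constant group: zero IQR
})

test_that("generator-truth medians are recovered from synthetic masks", {
  cfg <- mask_config(n_cells = 60, seed = 21,
                     area_distribution = c(420, 60),
                     aspect_ratio_distribution = c(4.8, 0.4),
                     image_height_px = 900, image_width_px = 900)
  mk <- generate_cell_mask(cfg)
  sh <- shape_descriptors(mk$mask) |> filter_by_area(200)
  expect_gt(nrow(sh), 30)
  expect_lt(abs(median(sh$aspect_ratio) - median(mk$truth$aspect_ratio)),
            0.5)
})
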