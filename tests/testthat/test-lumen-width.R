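test_that("profile grid has the expected counts and margins", {
  # extent 1850 um: 741 rows at 2.5 um/px
  expect_identical(nrow(extract_profiles(741, pixel_size = 2.5,
                                         spacing = 25, margin = 0)), 75L)
  # extent 2000 um with 100 um margins: 73 points in [100, 1900]
  g <- extract_profiles(801, pixel_size = 2.5, spacing = 25, margin = 100)
  expect_identical(nrow(g), 73L)
  expect_equal(range(g$position_um), c(100, 1900))
  # spacing beyond the usable extent: single profile at the first point
  g1 <- extract_profiles(101, pixel_size = 2, spacing = 1e4, margin = 20)
  expect_identical(nrow(g1), 1L)
  expect_equal(g1$position_um, 20)
  expect_error(extract_profiles(101, pixel_size = 2, spacing = 25,
                                margin = 150), "margin")
})

test_that("wider margins never add profiles", {
  n_prev <- Inf
  for (m in c(0, 50, 100, 200, 400)) {
    n <- nrow(extract_profiles(600, pixel_size = 3.25, spacing = 25,
                               margin = m))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("edge detection follows the outermost-qualifying-run rule", {
  prof <- c(rep(0, 100), rep(1, 400), rep(0, 100))
  e <- detect_lumen_edges(prof, threshold = 0.5)
  expect_true(e$valid)
  expect_identical(c(e$left_px, e$right_px), c(101L, 500L))

  expect_false(detect_lumen_edges(rep(0.2, 50), 0.5)$valid)

  # a single hot pixel is ignored under min_run_px = 3
  hot <- rep(0, 60); hot[30] <- 10
  expect_false(detect_lumen_edges(hot, 0.5, min_run_px = 3)$valid)
  expect_true(detect_lumen_edges(hot, 0.5, min_run_px = 1)$valid)

  # two qualifying runs: edges bracket both (outermost rule)
  two <- rep(0, 100); two[11:20] <- 1; two[71:90] <- 1
  e2 <- detect_lumen_edges(two, 0.5)
  expect_identical(c(e2$left_px, e2$right_px), c(11L, 90L))
})

test_that("raising min_run_px never increases the number of valid profiles", {
  set.seed(7)
  profs <- replicate(30, {
    p <- rep(0, 120)
    for (k in seq_len(sample(1:4, 1))) {
      s <- sample(1:110, 1); p[s:min(s + sample(0:8, 1), 120)] <- 1
    }
    p
  }, simplify = FALSE)
  n_prev <- Inf
  for (mr in c(1, 2, 4, 8)) {
    n <- sum(vapply(profs, function(p)
      detect_lumen_edges(p, 0.5, mr)$valid, logical(1)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("projected width is the pixel separation times pixel size", {
  expect_equal(projected_width(10, 410, 3.25), 1300)
  expect_equal(projected_width(5, 5, 3.25), 0)
  expect_equal(projected_width(0, 100, 2), 200)
  expect_error(projected_width(100, 10, 1), "reversed")
})

test_that("a wall-to-wall band measures exactly the wall separation", {
  sc <- tiny_scene(width_um = 780)           # 240 px * 3.25 = full channel
  m <- measure_image(sc$image)
  expect_equal(m$mean_width, 780)
  expect_identical(m$n_valid_profiles, m$n_profiles)
  expect_equal(sc$true_mean_width, 780)
})

test_that("audit counts add up and the per-profile table is complete", {
  sc <- tiny_scene(width_um = 400)
  m <- measure_image(sc$image)
  pr <- tidy(m)
  expect_identical(nrow(pr), m$n_profiles)
  expect_identical(sum(pr$valid) + sum(!pr$valid), m$n_profiles)
  expect_identical(sum(pr$valid), m$n_valid_profiles)
  expect_equal(glance(m)$mean_width_um, mean(pr$width_um[pr$valid]))
})

test_that("common rescaling of intensities leaves detected edges unchanged", {
  sc <- tiny_scene(width_um = 500, noise_sd = 0.03, seed = 11)
  m1 <- measure_image(sc$image)
  img2 <- sc$image
  img2$fluorescence <- img2$fluorescence * 37.5
  m2 <- measure_image(img2)
  expect_identical(tidy(m1)$left_px, tidy(m2)$left_px)
  expect_identical(tidy(m1)$right_px, tidy(m2)$right_px)
})

test_that("an image with no qualifying run yields a measurement error", {
  # checkerboard: supra-threshold runs all have length 1 < min_run_px
  chk <- outer(1:100, 1:50, function(i, j) (i + j) %% 2)
  img <- channel_image(chk, pixel_size = 3.25, chip_id = "empty")
  expect_error(measure_image(img, margin = 0, spacing = 50), "empty")
})

test_that("wall detection recovers synthetic walls and honors manual mode", {
  sc <- tiny_scene()
  cal <- detect_wall(sc$image)
  expect_s3_class(cal, "wall_calibration")
  expect_lte(abs(cal$wall_left_x - 41), 2)
  expect_identical(cal$source, "automatic")

  expect_error(detect_wall(matrix(0.5, 50, 50)), "manual")

  man <- wall_calibration(123)
  expect_identical(detect_wall(sc$image, manual = man), man)
  expect_identical(man$source, "manual")
})
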