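test_that("one group, one day reduces to the sample mean with a symmetric CI", {
  cohort <- tibble::tibble(chip_id = c("a", "b", "c"), group = "control",
                           day = 5L, width_um = c(1290, 1300, 1310))
  fit <- fit_lmm(cohort)
  p <- tidy(fit)
  expect_identical(nrow(p), 1L)
  expect_equal(p$estimate, 1300)
  expect_equal(p$upper - p$estimate, p$estimate - p$lower)
  expect_identical(p$n, 3L)
})

test_that("balanced complete data recover the per-cell sample means", {
  des <- cohort_design(
    days = c(2, 3, 5),
    means = list(control = c(1300, 1295, 1290),
                 `co-culture` = c(1300, 1270, 1240)),
    covariance = {
      s <- c(10, 15, 20)
      diag(s) %*% outer(1:3, 1:3, function(i, j) 0.6^abs(i - j)) %*% diag(s)
    },
    n_chips = c(control = 20, `co-culture` = 20), seed = 12)
  co <- generate_cohort(des)
  fit <- fit_lmm(co)
  cell_means <- describe_widths(co)
  joined <- dplyr::left_join(tidy(fit), cell_means, by = c("day", "group"))
  expect_equal(joined$estimate, joined$mean_um, tolerance = 1e-6)
})

test_that("the estimated covariance tracks the design covariance", {
  s <- c(10, 15, 20)
  Sig <- diag(s) %*% outer(1:3, 1:3, function(i, j) 0.6^abs(i - j)) %*% diag(s)
  des <- cohort_design(days = c(2, 3, 5),
                       means = list(g = c(1300, 1280, 1260)),
                       covariance = Sig, n_chips = c(g = 150), seed = 5)
  fit <- fit_lmm(generate_cohort(des))
  expect_true(isSymmetric(fit$covariance, tol = 1e-8))
  expect_true(min(eigen(fit$covariance, only.values = TRUE)$values) >= 0)
  expect_lt(max(abs(fit$covariance - Sig) / Sig[3, 3]), 0.25)
})

test_that("divergence day follows the closed-interval overlap rule", {
  # identical predictions: never diverges
  same <- tibble::tibble(day = rep(c(2L, 3L), each = 2),
                         group = rep(c("a", "b"), 2),
                         lower = 10, upper = 20)
  expect_true(is.na(ci_divergence_day(same)$first_divergence_day))

  # reported day-6 interval bounds: earlier days overlap, day 6 does not
  paper_like <- tibble::tibble(
    day = rep(c(5L, 6L), each = 2),
    group = rep(c("HUVEC-only", "triple"), 2),
    lower = c(1280, 1250, 1283.53, 1247.35),
    upper = c(1320, 1300, 1394.714, 1276.41))
  div <- ci_divergence_day(paper_like)
  expect_identical(div$first_divergence_day, 6L)
  expect_identical(div$per_day$overlap, c(TRUE, FALSE))

  # touching intervals count as overlap (conservative closed intervals)
  touch <- tibble::tibble(day = c(2L, 2L), group = c("a", "b"),
                          lower = c(0, 10), upper = c(10, 20))
  expect_true(is.na(ci_divergence_day(touch)$first_divergence_day))

  single <- tibble::tibble(day = 2L, group = "a", lower = 0, upper = 1)
  expect_error(ci_divergence_day(single), "two groups")
})

test_that("width summaries use the n-1 sd and undefined sd for n = 1", {
  cohort <- tibble::tibble(
    chip_id = c("a", "b", "c", "d"),
    group = c("g1", "g1", "g1", "g2"),
    day = 2L,
    width_um = c(1290, 1300, 1310, 1250))
  s <- describe_widths(cohort)
  g1 <- s[s$group == "g1", ]
  expect_equal(g1$mean_um, 1300)
  expect_equal(g1$sd_um, 10)
  g2 <- s[s$group == "g2", ]
  expect_equal(g2$mean_um, 1250)
  expect_true(is.na(g2$sd_um))
})

test_that("cohort validation rejects malformed tables", {
  expect_error(fit_lmm(tibble::tibble(chip_id = "a", day = 1)), "columns")
  dup <- tibble::tibble(chip_id = c("a", "a"), group = "g", day = c(2L, 2L),
                        width_um = c(1, 2))
  expect_error(fit_lmm(dup), "duplicate")
  two_groups <- tibble::tibble(chip_id = "a", group = c("g1", "g2"),
                               day = c(2L, 3L), width_um = c(1, 2))
  expect_error(fit_lmm(two_groups), "exactly one group")
})

test_that("final-day generator mean is recovered within Monte-Carlo tolerance", {
  co <- generate_cohort(soc_cohort_design(seed = 19))
  s <- describe_widths(co)
  final <- s[s$group == "co-culture" & s$day == 10, ]
  # n = 26 chips at sd ~100 um: se ~ 20 um
  expect_lt(abs(final$mean_um - 1023.11), 60)
})
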