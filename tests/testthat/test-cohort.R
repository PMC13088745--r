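test_that("the reference design reproduces the study's per-day chip counts", {
  co <- generate_cohort(soc_cohort_design(seed = 1))
  counts <- dplyr::count(co, group, day)
  ctrl <- counts$n[counts$group == "control"][order(
    counts$day[counts$group == "control"])]
  cocu <- counts$n[counts$group == "co-culture"][order(
    counts$day[counts$group == "co-culture"])]
  expect_identical(cocu, c(68L, 68L, 65L, 62L, 34L, 34L, 33L, 26L))
  expect_identical(ctrl, c(13L, 13L, 6L, 6L, 6L, 6L, 6L, 6L))
})

test_that("dropout is monotone: each chip's series is a leading block", {
  co <- generate_cohort(soc_cohort_design(seed = 4))
  days <- sort(unique(co$day))
  by_chip <- split(co$day, co$chip_id)
  for (s in by_chip) {
    expect_identical(sort(s), days[seq_along(s)])
  }
})

test_that("identical group trajectories show no systematic difference", {
  mu <- c(1300, 1290, 1280)
  des <- cohort_design(
    days = c(2, 3, 5),
    means = list(a = mu, b = mu),
    covariance = diag(c(100, 150, 200)),
    n_chips = c(a = 150, b = 150), seed = 10)
  diffs <- vapply(1:8, function(s) {
    des$seed <- s
    co <- generate_cohort(des)
    m <- tapply(co$width_um, co$group, mean)
    m[["a"]] - m[["b"]]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2)     # se of the mean diff ~ 0.35 per rep
})

test_that("sample covariance converges to the design covariance", {
  sds <- c(10, 20, 30)
  R <- outer(1:3, 1:3, function(i, j) 0.5^abs(i - j))
  Sig <- diag(sds) %*% R %*% diag(sds)
  des <- cohort_design(days = c(1, 2, 3),
                       means = list(g = c(0, 0, 0)),
                       covariance = Sig, n_chips = c(g = 2000), seed = 6)
  co <- generate_cohort(des)
  wide <- tidyr::pivot_wider(co, names_from = day, values_from = width_um)
  S <- stats::cov(as.matrix(wide[, c("1", "2", "3")]))
  expect_lt(max(abs(S - Sig)), 40)   # Monte-Carlo tolerance at n = 2000
})

test_that("cohort generation is seed-deterministic and validated", {
  a <- generate_cohort(soc_cohort_design(seed = 3))
  b <- generate_cohort(soc_cohort_design(seed = 3))
  expect_identical(a, b)

  expect_error(cohort_design(days = 1:2, means = list(g = c(0, 0)),
                             covariance = matrix(c(1, 2, 2, 1), 2),
                             n_chips = c(g = 5)),
               "positive definite")
  expect_error(cohort_design(days = 1:2, means = list(g = c(0, 0)),
                             covariance = diag(2),
                             retained = list(g = c(3L, 5L))),
               "non-increasing")
})
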