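kw_df <- function(groups) {
  data.frame(value = unlist(groups),
             grp = rep(names(groups), lengths(groups)))
}

test_that("the worked three-group example gives H = 4.571", {
  df <- kw_df(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
  res <- kruskal_dunn(df, value, grp)
  expect_equal(round(res$H, 3), 4.571)
  expect_equal(res$H, hand_kruskal_H(list(c(1, 2), c(3, 4), c(5, 6))),
               tolerance = 1e-12)
  expect_identical(res$df, 2L)
})

test_that("H and p agree with the reference implementation incl. ties", {
  set.seed(55)
  for (i in 1:10) {
    groups <- lapply(1:3, function(k) round(rnorm(sample(5:12, 1), k), 0))
    names(groups) <- c("a", "b", "c")
    df <- kw_df(groups)
    res <- kruskal_dunn(df, value, grp)
    ref <- stats::kruskal.test(df$value, factor(df$grp))
    expect_equal(res$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ranks make the test invariant under monotone transforms", {
  set.seed(77)
  df <- kw_df(list(a = runif(8, 1, 2), b = runif(10, 1.2, 2.4),
                   c = runif(7, 1.5, 3)))
  base <- kruskal_dunn(df, value, grp)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) 5 * x - 2)) {
    df2 <- df; df2$value <- f(df2$value)
    res <- kruskal_dunn(df2, value, grp)
    expect_equal(res$H, base$H, tolerance = 1e-12)
    expect_equal(res$comparisons$z, base$comparisons$z, tolerance = 1e-12)
  }
})

test_that("with two groups H equals the squared normal rank-sum statistic", {
  set.seed(91)
  for (i in 1:5) {
    df <- kw_df(list(a = rnorm(7), b = rnorm(9, 0.8)))
    res <- kruskal_dunn(df, value, grp)
    # the single Dunn z IS the normal-approximation rank statistic
    expect_equal(res$comparisons$z^2, res$H, tolerance = 1e-10)
  }
})

test_that("adjusted p-values never fall below unadjusted and stars match", {
  set.seed(13)
  df <- kw_df(list(a = rnorm(12), b = rnorm(12, 1), c = rnorm(12, 3),
                   d = rnorm(12, 3.1)))
  res <- kruskal_dunn(df, value, grp)
  expect_true(all(res$comparisons$p_adjusted >=
                    res$comparisons$p_unadjusted - 1e-15))
  expected_stars <- ifelse(res$comparisons$p_adjusted < 0.001, "***",
                    ifelse(res$comparisons$p_adjusted < 0.01, "**",
                    ifelse(res$comparisons$p_adjusted < 0.05, "*", "ns")))
  expect_identical(res$comparisons$stars, expected_stars)
})

test_that("degenerate all-identical data raise an error", {
  df <- kw_df(list(a = c(3, 3, 3), b = c(3, 3), c = c(3, 3, 3)))
  expect_error(kruskal_dunn(df, value, grp), "degenerate")
  expect_error(kruskal_dunn(kw_df(list(a = 1:3)), value, grp),
               "two groups")
})
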