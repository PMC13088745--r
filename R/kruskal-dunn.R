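#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Rank-based one-way comparison of two or more groups followed by
#' Dunn's pairwise z tests, both with the usual tie correction.  The H
#' statistic is
#' `H = (12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)) / (1 - sum(t^3 - t) / (N^3 - N))`
#' with `R_i` the group rank sums and `t` the tie-group sizes, referred
#' to a chi-square with k - 1 degrees of freedom.  Dunn's statistic for
#' groups i, j is the difference of mean ranks over
#' `sqrt((N (N + 1) / 12 - sum(t^3 - t) / (12 (N - 1))) (1/n_i + 1/n_j))`,
#' with two-sided normal p-values adjusted for multiplicity (Bonferroni
#' by default; unadjusted values are also reported).  Significance
#' stars: `***` < 0.001, `**` < 0.01, `*` < 0.05, `ns` otherwise.
#'
#' @param data a data frame.
#' @param value,group column names, given unquoted (tidy evaluation) or
#'   as strings: the descriptor being compared and the grouping
#'   variable.
#' @param p_adjust multiplicity adjustment passed to
#'   [stats::p.adjust()].
#' @return A `kw_dunn` object: `H`, `df`, `p_value`, `n`, `groups`
#'   (tibble: group, n, mean rank) and `comparisons` (tibble: pair, z,
#'   `p_unadjusted`, `p_adjusted`, `stars`).  `tidy()` returns the
#'   comparisons, `glance()` the global test.
#' @examples
#' df <- data.frame(v = c(1, 2, 3, 4, 5, 6),
#'                  g = rep(c("a", "b", "c"), each = 2))
#' kruskal_dunn(df, v, g)
#' @export
kruskal_dunn <- function(data, value, group, p_adjust = "bonferroni") {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  # accept column names given as strings
  if (is.character(v) && length(v) == 1 && v %in% names(data)) v <- data[[v]]
  if (is.character(g) && length(g) == 1 && g %in% names(data)) g <- data[[g]]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- factor(g[keep])
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups.", call. = FALSE)
  if (any(table(g) < 1)) stop("every group needs at least one value.",
                              call. = FALSE)
  N <- length(v)
  rk <- rank(v)
  ties <- table(v)
  tie_sum <- sum(ties^3 - ties)
  C <- 1 - tie_sum / (N^3 - N)
  if (C <= 0) {
    stop("degenerate data: all observations identical (tie correction vanishes).",
         call. = FALSE)
  }
  n_i <- as.vector(table(g))
  R_i <- as.vector(tapply(rk, g, sum))
  H <- (12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)) / C
  p_global <- pchisq(H, df = k - 1, lower.tail = FALSE)

  mean_rank <- R_i / n_i
  lev <- levels(g)
  pairs <- utils::combn(k, 2)
  sig2 <- (N * (N + 1) / 12 - tie_sum / (12 * (N - 1)))
  z <- (mean_rank[pairs[1, ]] - mean_rank[pairs[2, ]]) /
    sqrt(sig2 * (1 / n_i[pairs[1, ]] + 1 / n_i[pairs[2, ]]))
  p_un <- 2 * pnorm(-abs(z))
  p_ad <- stats::p.adjust(p_un, method = p_adjust)
  comparisons <- tibble::tibble(
    group1 = lev[pairs[1, ]], group2 = lev[pairs[2, ]],
    z = z, p_unadjusted = p_un, p_adjusted = p_ad,
    stars = significance_stars(p_ad))

  structure(list(
    H = H, df = k - 1L, p_value = p_global, n = N,
    groups = tibble::tibble(group = lev, n = n_i, mean_rank = mean_rank),
    comparisons = comparisons, p_adjust = p_adjust
  ), class = "kw_dunn")
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf(
    "<kw_dunn> Kruskal-Wallis H = %.3f (df = %d, N = %d), p = %.4g\n",
    x$H, x$df, x$n, x$p_value))
  cat(sprintf("Dunn's post-hoc (%s-adjusted):\n", x$p_adjust))
  print(x$comparisons)
  invisible(x)
}

#' @rdname kruskal_dunn
#' @param x a `kw_dunn`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.kw_dunn <- function(x, ...) x$comparisons

#' @rdname kruskal_dunn
#' @exportS3Method generics::glance
glance.kw_dunn <- function(x, ...) {
  tibble::tibble(H = x$H, df = x$df, p_value = x$p_value, n = x$n,
                 n_groups = nrow(x$groups), p_adjust = x$p_adjust)
}
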