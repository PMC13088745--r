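#' Repeated-measures linear mixed model with unstructured covariance
#'
#' Fits the saturated day-by-group cell-means model to a longitudinal
#' per-chip width table by restricted maximum likelihood, with a common
#' unstructured covariance across days shared by all chips (a free
#' variance per day and a free correlation per day pair) and no random
#' effects.  Chips with incomplete (monotone-dropout) series contribute
#' their observed entries through the direct likelihood, which is valid
#' under ignorable (MAR) missingness.  Day and group are treated as
#' categorical, so the fixed-effect structure day + group + day:group is
#' estimated through its equivalent cell-means parameterisation.
#' Per-cell predictions carry Wald (normal-quantile) confidence
#' intervals.
#'
#' Estimation groups chips by missingness pattern and maximizes the
#' restricted likelihood over the covariance's Cholesky factor by
#' quasi-Newton iteration, profiling the generalized-least-squares cell
#' means at each step; pattern-level sufficient statistics make the fit
#' time independent of cohort size.
#'
#' @param cohort tibble/data frame with columns `chip_id`, `group`,
#'   `day`, `width_um` (one row per chip-day; `(chip_id, day)` unique,
#'   each chip in exactly one group).
#' @param ci_level confidence level for the per-cell intervals.
#' @return A `lumen_lmm` object with elements `predictions` (tibble:
#'   `day`, `group`, `estimate`, `se`, `lower`, `upper`, `n`),
#'   `covariance` (estimated day-by-day matrix, um^2), `fit` (the raw
#'   estimator output, including the restricted log-likelihood), `days`,
#'   `groups`, `ci_level`, `method`.  `tidy()` returns the predictions,
#'   `glance()` a one-row fit summary.
#' @examples
#' fit <- fit_lmm(generate_cohort(soc_cohort_design(seed = 3)))
#' tidy(fit)
#' @export
fit_lmm <- function(cohort, ci_level = 0.95) {
  cohort <- validate_cohort(cohort)
  days <- sort(unique(cohort$day))
  groups <- sort(unique(cohort$group))
  d <- cohort
  d$day_f <- factor(d$day, levels = days)
  d$group_f <- factor(d$group, levels = groups)
  d$cell <- interaction(d$day_f, d$group_f, sep = "@@")
  d$tindex <- match(d$day, days)

  fit <- tryCatch(
    reml_fit_unstructured(d, days, groups),
    error = function(e) {
      stop(sprintf(
        "mixed-model fit failed (%s); %d observations, %d chips, %d days.",
        conditionMessage(e), nrow(d), length(unique(d$chip_id)), length(days)),
        call. = FALSE)
    })

  z <- qnorm(1 - (1 - ci_level) / 2)
  counts <- dplyr::count(d, .data$day_f, .data$group_f, .drop = FALSE)
  predictions <- purrr::map_dfr(groups, function(g) {
    tibble::tibble(day = days, group = g,
                   estimate = fit$beta[[g]],
                   se = sqrt(diag(fit$vcov[[g]])))
  }) |>
    dplyr::mutate(lower = .data$estimate - z * .data$se,
                  upper = .data$estimate + z * .data$se) |>
    dplyr::left_join(
      tibble::tibble(day = as.integer(as.character(counts$day_f)),
                     group = as.character(counts$group_f), n = counts$n),
      by = c("day", "group")) |>
    dplyr::arrange(.data$day, .data$group)

  Sigma <- fit$Sigma
  dimnames(Sigma) <- list(days, days)

  structure(list(
    predictions = predictions,
    covariance = Sigma,
    fit = fit,
    days = days, groups = groups, ci_level = ci_level,
    method = "REML", converged = TRUE,
    n_obs = nrow(d), n_chips = length(unique(d$chip_id))
  ), class = "lumen_lmm")
}

validate_cohort <- function(cohort) {
  need <- c("chip_id", "group", "day", "width_um")
  if (!all(need %in% names(cohort))) {
    stop("cohort needs columns chip_id, group, day, width_um.", call. = FALSE)
  }
  cohort <- tibble::as_tibble(cohort)
  if (anyDuplicated(cohort[c("chip_id", "day")])) {
    stop("duplicate (chip_id, day) rows in the cohort.", call. = FALSE)
  }
  gpc <- tapply(cohort$group, cohort$chip_id,
                function(g) length(unique(g)))
  if (any(gpc > 1)) {
    stop("each chip must belong to exactly one group.", call. = FALSE)
  }
  cohort
}

#' @export
print.lumen_lmm <- function(x, ...) {
  cat(sprintf(
    "<lumen_lmm> %s fit: %d obs, %d chips, %d days x %d groups; %.0f%% Wald CIs\n",
    x$method, x$n_obs, x$n_chips, length(x$days), length(x$groups),
    100 * x$ci_level))
  print(x$predictions, n = Inf)
  invisible(x)
}

#' @rdname fit_lmm
#' @param x a `lumen_lmm`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.lumen_lmm <- function(x, ...) x$predictions

#' @rdname fit_lmm
#' @exportS3Method generics::glance
glance.lumen_lmm <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_chips = x$n_chips,
                 n_days = length(x$days), n_groups = length(x$groups),
                 method = x$method, converged = x$converged,
                 logLik = x$fit$logLik,
                 AIC = -2 * x$fit$logLik + 2 * x$fit$n_par,
                 ci_level = x$ci_level)
}

#' First day at which the two groups' confidence intervals separate
#'
#' Applies the interval-overlap rule: per day the two groups' confidence
#' intervals are compared as closed intervals (exactly touching
#' endpoints still count as overlap, a conservative convention), and the
#' divergence day is the earliest day whose intervals do not overlap
#' (`NA` if they always do).
#'
#' @param fit a [fit_lmm()] result, or a data frame with columns `day`,
#'   `group`, `lower`, `upper` for exactly two groups.
#' @return A `divergence_result`: tibble `per_day` (`day`, per-group
#'   bounds, `overlap`) and `first_divergence_day` (integer or `NA`).
#' @export
ci_divergence_day <- function(fit) {
  preds <- if (inherits(fit, "lumen_lmm")) fit$predictions else
    tibble::as_tibble(fit)
  stopifnot(all(c("day", "group", "lower", "upper") %in% names(preds)))
  groups <- sort(unique(preds$group))
  if (length(groups) != 2) {
    stop("interval-overlap divergence needs exactly two groups.",
         call. = FALSE)
  }
  wide <- preds |>
    dplyr::select(dplyr::all_of(c("day", "group", "lower", "upper"))) |>
    tidyr::pivot_wider(names_from = "group",
                       values_from = c("lower", "upper")) |>
    dplyr::arrange(.data$day)
  lo1 <- wide[[paste0("lower_", groups[1])]]
  up1 <- wide[[paste0("upper_", groups[1])]]
  lo2 <- wide[[paste0("lower_", groups[2])]]
  up2 <- wide[[paste0("upper_", groups[2])]]
  if (anyNA(c(lo1, up1, lo2, up2))) {
    stop("both groups must be predicted on a shared day grid.", call. = FALSE)
  }
  wide$overlap <- pmax(lo1, lo2) <= pmin(up1, up2)
  first <- wide$day[which(!wide$overlap)[1]]
  structure(list(per_day = wide,
                 first_divergence_day = if (length(first) && !is.na(first))
                   first else NA_integer_),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  if (is.na(x$first_divergence_day)) {
    cat("<divergence_result> confidence intervals overlap at every day\n")
  } else {
    cat(sprintf("<divergence_result> first non-overlap at day %s\n",
                x$first_divergence_day))
  }
  print(x$per_day)
  invisible(x)
}

#' Per-day, per-group width summaries
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator) and
#' count per day-group cell.  A single-observation cell reports an
#' undefined (NA) standard deviation, never zero.
#'
#' @param cohort tibble with `chip_id`, `group`, `day`, `width_um`.
#' @return Tibble: `group`, `day`, `n`, `mean_um`, `sd_um`.
#' @export
describe_widths <- function(cohort) {
  cohort <- validate_cohort(cohort)
  cohort |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_um = mean(.data$width_um),
                     sd_um = sd(.data$width_um),
                     .groups = "drop") |>
    dplyr::arrange(.data$group, .data$day)
}
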