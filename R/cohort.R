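#' Design of a longitudinal two-group chip cohort
#'
#' Describes the repeated-measures structure of a lumen-width study: a
#' set of observation days, per-group mean width trajectories, a single
#' unstructured (symmetric positive-definite) covariance matrix shared by
#' all chips, and a monotone dropout schedule (chips leave the study and
#' never return, so each chip's series is a leading block of the day
#' grid).
#'
#' @param days ordered integer vector of observation days.
#' @param means named list, one numeric vector of per-day mean widths
#'   (um) per group.
#' @param covariance symmetric positive-definite matrix, one row/column
#'   per day, shared across groups (um^2).
#' @param retained named list, one integer vector per group giving the
#'   number of chips still observed at each day; must be non-increasing.
#'   `NULL` keeps every chip at every day (requires `n_chips`).
#' @param n_chips named integer vector of chips per group; defaults to
#'   the first entry of each group's `retained` schedule.
#' @param seed integer seed.
#' @return A `cohort_design` list.
#' @seealso [generate_cohort()], [soc_cohort_design()]
#' @export
cohort_design <- function(days, means, covariance, retained = NULL,
                          n_chips = NULL, seed = 1L) {
  days <- as.integer(days)
  nd <- length(days)
  groups <- names(means)
  stopifnot(nd >= 1, !is.null(groups), all(nzchar(groups)))
  for (g in groups) {
    if (length(means[[g]]) != nd) {
      stop(sprintf("means for group '%s' must have one value per day.", g),
           call. = FALSE)
    }
  }
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))) ||
      nrow(covariance) != nd) {
    stop("`covariance` must be a symmetric matrix with one row per day.",
         call. = FALSE)
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("`covariance` must be positive definite.", call. = FALSE)
  }
  if (is.null(retained)) {
    if (is.null(n_chips)) stop("supply `retained` or `n_chips`.", call. = FALSE)
    retained <- lapply(setNames(as.integer(n_chips[groups]), groups),
                       function(n) rep(n, nd))
  }
  for (g in groups) {
    r <- retained[[g]]
    if (length(r) != nd || any(diff(r) > 0) || any(r < 0)) {
      stop(sprintf(
        "retained counts for group '%s' must be non-increasing over days.", g),
        call. = FALSE)
    }
  }
  if (is.null(n_chips)) n_chips <- vapply(retained, max, integer(1))
  structure(list(days = days, groups = groups, means = means,
                 covariance = covariance, retained = retained,
                 n_chips = n_chips, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Reference synovium-on-chip cohort design
#'
#' The packaged default study conditions: days 2, 3, 5-10; a flat
#' control (endothelium-only) trajectory near the 1300 um channel width
#' anchored at the reported day-2 and day-10 control means, and a
#' remodelling co-culture trajectory anchored at the reported day-2,
#' day-5 and day-10 co-culture means with smooth interpolation between;
#' per-day standard deviations rising from ~10 um to ~100 um with
#' exponentially decaying inter-day correlation (0.7^|lag|); and the
#' reported per-day chip counts as a monotone dropout schedule
#' (control 13,13,6,6,6,6,6,6; co-culture 68,68,65,62,34,34,33,26).
#'
#' @param seed integer seed.
#' @return A [cohort_design()].
#' @export
soc_cohort_design <- function(seed = 1L) {
  days <- c(2L, 3L, 5L, 6L, 7L, 8L, 9L, 10L)
  sds <- c(9.8, 12, 16.5, 25, 45, 65, 85, 99.8)
  R <- outer(seq_along(days), seq_along(days),
             function(i, j) 0.7^abs(i - j))
  cohort_design(
    days = days,
    means = list(
      control      = c(1295.42, 1297, 1299, 1300, 1302, 1303, 1304, 1304.92),
      `co-culture` = c(1296.04, 1292, 1284.32, 1262, 1210, 1150, 1085, 1023.11)
    ),
    covariance = diag(sds) %*% R %*% diag(sds),
    retained = list(
      control      = c(13L, 13L, 6L, 6L, 6L, 6L, 6L, 6L),
      `co-culture` = c(68L, 68L, 65L, 62L, 34L, 34L, 33L, 26L)
    ),
    seed = seed
  )
}

#' Draw a longitudinal cohort of per-chip width series
#'
#' Each chip's full-series widths are drawn from a multivariate normal
#' with its group's mean trajectory and the shared unstructured
#' covariance; the dropout schedule then truncates chip i of a group to
#' the days at which at least i chips are retained (monotone
#' missingness).
#'
#' @param design a [cohort_design()].
#' @return A tibble with columns `chip_id`, `group`, `day`, `width_um`
#'   (one row per observed chip-day).
#' @examples
#' head(generate_cohort(soc_cohort_design(seed = 42)))
#' @export
generate_cohort <- function(design = soc_cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  withr::with_seed(design$seed, {
    purrr::map_dfr(design$groups, function(g) {
      n0 <- design$n_chips[[g]]
      ret <- design$retained[[g]]
      if (n0 == 0L) return(NULL)
      X <- MASS::mvrnorm(n0, mu = design$means[[g]],
                         Sigma = design$covariance)
      X <- matrix(X, nrow = n0)
      purrr::map_dfr(seq_len(n0), function(i) {
        keep <- which(i <= ret)
        if (length(keep) == 0L) return(NULL)
        tibble::tibble(
          chip_id = sprintf("%s_%03d", gsub("[^a-z0-9]+", "", g), i),
          group = g,
          day = design$days[keep],
          width_um = X[i, keep])
      })
    })
  })
}
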