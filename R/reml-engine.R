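# Restricted-maximum-likelihood engine for the repeated-measures model
# with saturated (day x group) cell means and one unstructured covariance
# matrix shared by all chips.  Chips are grouped by their missingness
# pattern (the subset of days observed), so one likelihood evaluation
# costs a handful of small Cholesky factorizations regardless of cohort
# size; the covariance is parameterized through its Cholesky factor with
# log-diagonal, keeping every iterate positive definite.

# Sufficient statistics per (group, observed-day pattern):
#   n   chips sharing the pattern
#   s   sum of observed vectors          (length k)
#   T   sum of outer products y y'       (k x k)
# plus the pattern's day indices.
reml_suffstats <- function(d, nd) {
  obs <- split(d[c("tindex", "width_um")], d$chip_id)
  grp_of <- vapply(split(d$group, d$chip_id), `[`, character(1), 1)
  stats <- list()
  for (chip in names(obs)) {
    o <- obs[[chip]]
    ord <- order(o$tindex)
    idx <- o$tindex[ord]
    y <- o$width_um[ord]
    key <- paste0(grp_of[[chip]], "|", paste(idx, collapse = ","))
    if (is.null(stats[[key]])) {
      stats[[key]] <- list(group = grp_of[[chip]], idx = idx, n = 0L,
                           s = numeric(length(idx)),
                           T = matrix(0, length(idx), length(idx)))
    }
    stats[[key]]$n <- stats[[key]]$n + 1L
    stats[[key]]$s <- stats[[key]]$s + y
    stats[[key]]$T <- stats[[key]]$T + tcrossprod(y)
  }
  stats
}

# theta <-> lower-triangular Cholesky factor of Sigma (log diagonal).
theta_to_sigma <- function(theta, nd) {
  L <- matrix(0, nd, nd)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

sigma_to_theta <- function(Sigma) {
  L <- t(chol(Sigma))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

# Negative restricted log-likelihood (up to an additive constant) and,
# as attributes, the GLS cell means and their covariance at this Sigma.
neg_reml <- function(theta, stats, nd, groups, want_beta = FALSE) {
  Sigma <- theta_to_sigma(theta, nd)
  A <- lapply(groups, function(g) matrix(0, nd, nd))
  names(A) <- groups
  b <- lapply(groups, function(g) numeric(nd))
  names(b) <- groups
  logdet <- 0
  # first pass: precision accumulators per group
  pat <- lapply(stats, function(st) {
    Sk <- Sigma[st$idx, st$idx, drop = FALSE]
    ch <- tryCatch(chol(Sk), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Pk <- chol2inv(ch)
    list(st = st, Pk = Pk, ld = 2 * sum(log(diag(ch))))
  })
  if (any(vapply(pat, is.null, logical(1)))) {
    return(structure(1e10, bad = TRUE))
  }
  for (p in pat) {
    st <- p$st
    logdet <- logdet + st$n * p$ld
    A[[st$group]][st$idx, st$idx] <- A[[st$group]][st$idx, st$idx] +
      st$n * p$Pk
    b[[st$group]][st$idx] <- b[[st$group]][st$idx] + p$Pk %*% st$s
  }
  quad <- 0
  reml_det <- 0
  beta <- list()
  vcov_beta <- list()
  for (g in groups) {
    chA <- tryCatch(chol(A[[g]]), error = function(e) NULL)
    if (is.null(chA)) return(structure(1e10, bad = TRUE))
    mu <- backsolve(chA, backsolve(chA, b[[g]], transpose = TRUE))
    reml_det <- reml_det + 2 * sum(log(diag(chA)))
    beta[[g]] <- as.vector(mu)
    if (want_beta) vcov_beta[[g]] <- chol2inv(chA)
    for (p in pat) {
      st <- p$st
      if (st$group != g) next
      mu_k <- beta[[g]][st$idx]
      quad <- quad + sum(p$Pk * st$T) -
        2 * sum(mu_k * (p$Pk %*% st$s)) +
        st$n * sum(mu_k * (p$Pk %*% mu_k))
    }
  }
  val <- 0.5 * (logdet + quad + reml_det)
  if (want_beta) {
    attr(val, "beta") <- beta
    attr(val, "vcov") <- vcov_beta
    attr(val, "Sigma") <- Sigma
  }
  val
}

# Analytic gradient of neg_reml with respect to theta.  With the cell
# means profiled out, the envelope theorem removes the d(beta)/d(Sigma)
# term, leaving per-pattern contributions
#   1/2 [ n P - P R P - n P (A^-1)_kk P ]
# with P the pattern precision, R the residual cross-product at the GLS
# means, and A the precision accumulator of the pattern's group; the
# chain rule maps the Sigma-gradient through Sigma = L L' with
# log-diagonal L.
neg_reml_grad <- function(theta, stats, nd, groups, want_beta = FALSE) {
  Sigma <- theta_to_sigma(theta, nd)
  A <- lapply(groups, function(g) matrix(0, nd, nd))
  names(A) <- groups
  b <- lapply(groups, function(g) numeric(nd))
  names(b) <- groups
  pat <- lapply(stats, function(st) {
    Sk <- Sigma[st$idx, st$idx, drop = FALSE]
    ch <- tryCatch(chol(Sk), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(st = st, Pk = chol2inv(ch))
  })
  if (any(vapply(pat, is.null, logical(1)))) {
    return(rep(0, length(theta)))          # flat direction at a bad point
  }
  for (p in pat) {
    st <- p$st
    A[[st$group]][st$idx, st$idx] <- A[[st$group]][st$idx, st$idx] +
      st$n * p$Pk
    b[[st$group]][st$idx] <- b[[st$group]][st$idx] + p$Pk %*% st$s
  }
  beta <- list()
  Ainv <- list()
  for (g in groups) {
    chA <- tryCatch(chol(A[[g]]), error = function(e) NULL)
    if (is.null(chA)) return(rep(0, length(theta)))
    beta[[g]] <- as.vector(backsolve(chA, backsolve(chA, b[[g]],
                                                    transpose = TRUE)))
    Ainv[[g]] <- chol2inv(chA)
  }
  G <- matrix(0, nd, nd)
  for (p in pat) {
    st <- p$st
    mu <- beta[[st$group]][st$idx]
    R <- st$T - tcrossprod(st$s, mu) - tcrossprod(mu, st$s) +
      st$n * tcrossprod(mu)
    Ak <- Ainv[[st$group]][st$idx, st$idx, drop = FALSE]
    Gk <- 0.5 * (st$n * p$Pk - p$Pk %*% R %*% p$Pk -
                   st$n * p$Pk %*% Ak %*% p$Pk)
    G[st$idx, st$idx] <- G[st$idx, st$idx] + Gk
  }
  L <- matrix(0, nd, nd)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  GL <- 2 * G %*% L
  diag(GL) <- diag(GL) * diag(L)           # log-diagonal chain rule
  GL[lower.tri(GL, diag = TRUE)]
}

# Moment-based starting covariance: within-cell residual covariance with
# pairwise-complete entries, shrunk toward its diagonal until positive
# definite.
init_sigma <- function(d, nd) {
  d$resid <- d$width_um - stats::ave(d$width_um, d$cell)
  M <- matrix(NA_real_, length(unique(d$chip_id)), nd)
  rownames(M) <- unique(d$chip_id)
  M[cbind(match(d$chip_id, rownames(M)), d$tindex)] <- d$resid
  S <- suppressWarnings(stats::cov(M, use = "pairwise.complete.obs"))
  v <- diag(S)
  v[!is.finite(v) | v <= 0] <- max(v[is.finite(v) & v > 0], 1)
  S[!is.finite(S)] <- 0
  diag(S) <- v
  D <- diag(v, nrow = nd)                  # nrow guards the nd = 1 case
  lam <- 0
  repeat {
    Ss <- (1 - lam) * S + lam * D
    ev <- eigen(Ss, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-6 * max(ev)) return(Ss)
    lam <- lam + 0.1
    if (lam > 1) return(D)
  }
}

# Full REML fit; returns cell means, their standard errors, the
# estimated covariance and the restricted log-likelihood.
reml_fit_unstructured <- function(d, days, groups) {
  nd <- length(days)
  stats <- reml_suffstats(d, nd)
  theta0 <- sigma_to_theta(init_sigma(d, nd))
  opt <- stats::optim(theta0, neg_reml, gr = neg_reml_grad, stats = stats,
                      nd = nd, groups = groups, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  if (opt$convergence != 0) {
    stop(sprintf("restricted-likelihood maximization did not converge (optim code %d).",
                 opt$convergence), call. = FALSE)
  }
  final <- neg_reml(opt$par, stats, nd, groups, want_beta = TRUE)
  if (isTRUE(attr(final, "bad"))) {
    stop("covariance estimate is singular at the optimum; refusing to regularize.",
         call. = FALSE)
  }
  n_obs <- nrow(d)
  p <- nd * length(groups)
  list(beta = attr(final, "beta"),
       vcov = attr(final, "vcov"),
       Sigma = attr(final, "Sigma"),
       logLik = -as.numeric(final) - (n_obs - p) / 2 * log(2 * pi),
       n_par = length(opt$par) + p,
       counts = opt$counts)
}
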