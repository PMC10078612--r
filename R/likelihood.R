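#' Total log-likelihood of a detrended, normalized trait panel
#'
#' Each year's vector of available trait values is modelled as a draw from
#' a zero-mean multivariate normal distribution whose correlation matrix
#' is the synchrony model ([build_sigma()]) restricted to the populations
#' observed that year; the total log-likelihood is the sum of the annual
#' log-likelihoods. Years in which only one population was observed
#' contribute a parameter-free standard-normal term (the diagonal is fixed
#' at 1), so they do not move the maximum but keep totals comparable
#' across parameter values. Because the set of available populations
#' varies among years, the more two series overlap, the more pairs of
#' years constrain their correlation.
#'
#' @param p A [synchrony_params()] object.
#' @param panel A detrended, normalized [trait_panel()] (see
#'   [detrend_normalize()]).
#' @param D Distance matrix in km aligned with `panel$populations`
#'   (checked against `rownames(D)` when present).
#' @param ridge Diagonal ridge added when a year's correlation matrix is
#'   numerically singular (with a warning); co-located sites with
#'   `rho0` near 1 can make the Cholesky fail.
#' @return The total log-likelihood (scalar).
#' @export
total_loglik <- function(p, panel, D, ridge = 1e-8) {
  validate_params(p)
  ctx <- loglik_context(panel, D)
  ll <- loglik_eval(c(p$rho0, p$rho_inf, p$l), ctx, ridge = ridge)
  if (ctx$ridge_count > 0) {
    warning(sprintf("numerically singular year covariance: ridge %g added (%d year group(s))",
                    ridge, ctx$ridge_count), call. = FALSE)
  }
  ll
}

# Precompute everything about (panel, D) that does not depend on the
# parameters: year groups sharing an availability pattern, the squared
# sub-distance matrix and the observed data block per group. Used by
# total_loglik, fit_synchrony and the parametric bootstrap.
loglik_context <- function(panel, D) {
  D <- as.matrix(D)
  k <- length(panel$populations)
  if (!identical(dim(D), c(k, k))) {
    stop("distance matrix dimension does not match panel populations")
  }
  # when D is labelled with the panel's populations, insist on alignment;
  # unlabelled or foreign-labelled matrices are taken as positional
  if (!is.null(rownames(D)) && all(panel$populations %in% rownames(D)) &&
      !identical(rownames(D), panel$populations)) {
    stop("distance matrix population order does not match panel; ",
         "reorder one of them")
  }
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")

  n_avail <- colSums(panel$mask)
  use <- which(n_avail >= 1)
  key <- apply(panel$mask[, use, drop = FALSE], 2, function(m)
    paste(which(m), collapse = ","))
  groups <- lapply(split(use, key), function(cols) {
    idx <- which(panel$mask[, cols[1]])
    kk <- length(idx)
    list(
      k = kk,
      n_years = length(cols),
      # populations x years block of observed values
      Y = panel$values[idx, cols, drop = FALSE],
      D2 = D[idx, idx, drop = FALSE]^2,
      diag_idx = seq.int(1L, kk * kk, by = kk + 1L)
    )
  })
  groups <- unname(groups)
  kk <- vapply(groups, `[[`, integer(1), "k")
  env <- new.env(parent = emptyenv())
  env$groups <- groups[kk > 1L]
  # single-population years contribute a parameter-free N(0,1) term
  env$const_ll <- sum(vapply(groups[kk == 1L], function(g)
    -0.5 * g$n_years * LOG2PI - 0.5 * sum(g$Y^2), numeric(1)))
  env$k <- k
  env$max_d <- if (k > 1) max(D) else 0
  env$ridge_count <- 0L
  env
}

LOG2PI <- log(2 * pi)

# Parameter vector theta = (rho0, rho_inf, l); ctx from loglik_context().
# The no-ridge path is tried first; on a Cholesky failure the whole
# evaluation is redone with a ridged diagonal (rare: near-singular Sigma).
loglik_eval <- function(theta, ctx, ridge = 1e-8) {
  ll <- tryCatch(loglik_eval_core(theta, ctx, 0),
                 error = function(e) NULL)
  if (is.null(ll)) {
    ctx$ridge_count <- ctx$ridge_count + 1L
    ll <- tryCatch(loglik_eval_core(theta, ctx, ridge),
                   error = function(e) -Inf)
  }
  ll
}

loglik_eval_core <- function(theta, ctx, ridge) {
  rho0 <- theta[1]; rho_inf <- theta[2]
  dr <- rho0 - rho_inf
  s <- -0.5 / (theta[3] * theta[3])
  ll <- ctx$const_ll
  for (g in ctx$groups) {
    sigma <- rho_inf + dr * exp(g$D2 * s)
    sigma[g$diag_idx] <- 1 + ridge
    R <- chol.default(sigma)
    z <- backsolve(R, g$Y, transpose = TRUE)
    ll <- ll - 0.5 * (g$n_years * (g$k * LOG2PI +
                                     2 * sum(log(R[g$diag_idx]))) +
                        sum(z * z))
  }
  ll
}
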