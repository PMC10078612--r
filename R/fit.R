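#' Fit the Gaussian correlogram by maximum likelihood
#'
#' Maximizes [total_loglik()] over the constrained parameter space
#' `0 <= rho_inf <= rho0 <= 1`, `0 < l <= l_max`. The optimizer works in
#' unconstrained coordinates (logit for `rho0`, `rho_inf` expressed as a
#' logit-scaled fraction of `rho0` to enforce the ordering, scaled logit
#' for `l`) and uses derivative-free Nelder-Mead local searches from a
#' space-filling set of starting points, since the likelihood surface can
#' be multimodal when few site pairs are informative about `l`. Estimates
#' landing on a constraint boundary (e.g. `rho_inf = 0`) are legitimate
#' and reported as-is.
#'
#' @param panel A detrended, normalized [trait_panel()].
#' @param D Distance matrix in km aligned with the panel populations.
#' @param starts Number of multi-start points (default 10).
#' @param l_max Upper bound for the spatial scale; default 5 times the
#'   maximum pairwise distance, beyond which the data cannot distinguish
#'   a large `l` from a flat correlogram.
#' @param start_seed Integer seed for the Latin-hypercube start design
#'   (fit is deterministic given this seed; the global RNG state is left
#'   untouched).
#' @param maxit Maximum Nelder-Mead iterations per start.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @return A list with `params` ([synchrony_params()]), `loglik`,
#'   `convergence` (number of converged starts), and `n_ridge` (count of
#'   singular-covariance ridge fallbacks during the search).
#' @export
fit_synchrony <- function(panel, D, starts = 10, l_max = NULL,
                          start_seed = 101L, maxit = 500, reltol = 1e-8) {
  if (length(panel$populations) < 2) {
    stop("synchrony fit needs at least 2 populations")
  }
  if (sum(colSums(panel$mask) >= 2) < 2) {
    stop("synchrony fit needs at least 2 years with >= 2 available populations")
  }
  ctx <- loglik_context(panel, D)
  if (is.null(l_max)) l_max <- 5 * ctx$max_d
  if (!is.finite(l_max) || l_max <= 0) stop("invalid l_max")

  th0 <- start_design(starts, l_max, ctx$max_d, start_seed)
  neg <- function(u) -loglik_eval(from_unconstrained(u, l_max), ctx)

  best <- NULL
  n_conv <- 0L
  for (s in seq_len(nrow(th0))) {
    u0 <- to_unconstrained(th0[s, ], l_max)
    res <- tryCatch(
      stats::optim(u0, neg, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (res$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (n_conv == 0L || is.null(best)) {
    stop("synchrony optimization failed to converge from any of ", starts,
         " starts (", length(panel$populations), " populations, ",
         length(panel$years), " years)")
  }
  theta <- from_unconstrained(best$par, l_max)
  list(
    params = synchrony_params(theta[1], theta[2], theta[3]),
    loglik = -best$value,
    convergence = n_conv,
    n_ridge = ctx$ridge_count
  )
}

# rho0 = plogis(u1); rho_inf = rho0 * plogis(u2); l = l_max * plogis(u3).
# plogis saturates to exactly 0/1 in double precision, so boundary
# estimates (rho_inf = 0) are reachable.
from_unconstrained <- function(u, l_max) {
  rho0 <- stats::plogis(u[1])
  c(rho0, rho0 * stats::plogis(u[2]), l_max * stats::plogis(u[3]))
}

to_unconstrained <- function(theta, l_max) {
  clamp <- function(x) pmin(pmax(x, 1e-12), 1 - 1e-12)
  c(stats::qlogis(clamp(theta[1])),
    stats::qlogis(clamp(theta[2] / theta[1])),
    stats::qlogis(clamp(theta[3] / l_max)))
}

# Space-filling start design over the constrained box. Latin hypercube in
# (rho0, rho_inf/rho0, log l), with l between a small fraction of the
# maximum pairwise distance and l_max.
start_design <- function(starts, l_max, max_d, seed) {
  stopifnot(starts >= 1)
  u <- withr::with_seed(seed, lhs::randomLHS(starts, 3))
  l_lo <- max(max_d / 50, l_max / 1000)
  cbind(
    0.05 + 0.9 * u[, 1],
    (0.05 + 0.9 * u[, 1]) * (0.02 + 0.9 * u[, 2]),
    exp(log(l_lo) + u[, 3] * (log(l_max * 0.98) - log(l_lo)))
  )
}
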