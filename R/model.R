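#' Gaussian correlogram parameters
#'
#' The spatial synchrony model assumes that the correlation between the
#' detrended, normalized trait fluctuations of two populations separated
#' by distance `d` (km) is
#' \deqn{\rho(d) = \rho_\infty + (\rho_0 - \rho_\infty)\, e^{-d^2 / (2 l^2)}}
#' where `rho0` is the correlation as distance approaches zero, `rho_inf`
#' the correlation as distance approaches infinity (a regional, fully
#' shared component), and `l` (km) is the standard deviation of the
#' Gaussian decay kernel — the characteristic distance over which
#' fluctuations remain correlated. All three parameters are restricted to
#' be positive, with `0 <= rho_inf <= rho0 <= 1`. With unit variances on
#' the diagonal, `1 - rho0` is a nugget: purely local, unshared
#' variability.
#'
#' @param rho0 Correlation at zero distance, in `[0, 1]`.
#' @param rho_inf Correlation at infinite distance, in `[0, rho0]`.
#' @param l Spatial scale in kilometers, `> 0`.
#' @return An object of class `synchrony_params`.
#' @export
synchrony_params <- function(rho0, rho_inf, l) {
  p <- structure(list(rho0 = as.numeric(rho0), rho_inf = as.numeric(rho_inf),
                      l = as.numeric(l)),
                 class = "synchrony_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  with(p, {
    if (!is.finite(rho0) || !is.finite(rho_inf) || !is.finite(l)) {
      stop("non-finite synchrony parameters")
    }
    if (rho0 < 0 || rho0 > 1) stop("rho0 must lie in [0, 1]")
    if (rho_inf < 0 || rho_inf > rho0) stop("rho_inf must lie in [0, rho0]")
    if (l <= 0) stop("l must be positive")
  })
  invisible(p)
}

#' @export
print.synchrony_params <- function(x, ...) {
  cat(sprintf("synchrony parameters: rho0 = %.3f, rho_inf = %.3f, l = %.1f km\n",
              x$rho0, x$rho_inf, x$l))
  invisible(x)
}

#' @export
as.numeric.synchrony_params <- function(x, ...) {
  c(rho0 = x$rho0, rho_inf = x$rho_inf, l = x$l)
}

#' Model correlation at a given distance
#'
#' Evaluates the Gaussian correlogram (see [synchrony_params()]) at one or
#' more distances.
#'
#' @param p A [synchrony_params()] object.
#' @param d Distance(s) in kilometers, `>= 0`.
#' @return Correlation(s) in `[rho_inf, rho0]`, non-increasing in `d`.
#' @export
correlation_at_distance <- function(p, d) {
  validate_params(p)
  if (any(d < 0)) stop("distance must be non-negative")
  p$rho_inf + (p$rho0 - p$rho_inf) * exp(-d^2 / (2 * p$l^2))
}

#' Model correlation matrix for a set of populations
#'
#' Builds the year-level correlation matrix of the synchrony model: unit
#' diagonal, off-diagonal entries given by [correlation_at_distance()] at
#' the pairwise distances. The result is positive semidefinite for every
#' valid parameter set and site layout, since it decomposes as
#' `rho_inf * J + (rho0 - rho_inf) * K + (1 - rho0) * I` with `J` the
#' all-ones matrix and `K` a Gaussian kernel matrix, all PSD.
#'
#' @param p A [synchrony_params()] object.
#' @param D Distance matrix in km (symmetric, zero diagonal), e.g. from
#'   [distance_matrix()].
#' @return Correlation matrix of the same dimension as `D`.
#' @export
build_sigma <- function(p, D) {
  validate_params(p)
  D <- as.matrix(D)
  sigma <- correlation_at_distance(p, D)
  diag(sigma) <- 1
  sigma
}
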