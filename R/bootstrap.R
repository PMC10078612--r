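#' Simulate a panel from the synchrony model
#'
#' Draws each year's vector of available populations from the zero-mean
#' multivariate normal distribution with correlation matrix
#' [build_sigma()] restricted to that year's availability set. This is the
#' data-generating step of the parametric bootstrap: the observed
#' missingness pattern is respected exactly.
#'
#' @param p A [synchrony_params()] object.
#' @param mask Logical populations x years availability matrix (e.g.
#'   `panel$mask`).
#' @param D Distance matrix in km aligned with the mask rows.
#' @param years Optional year labels (default from mask columns).
#' @param populations Optional population ids (default from mask rows).
#' @param name Panel name for the result.
#' @return A [trait_panel()] with the given mask.
#' @export
simulate_mvn_panel <- function(p, mask, D, years = NULL, populations = NULL,
                               name = "simulated") {
  validate_params(p)
  mask <- as.matrix(mask)
  if (is.null(populations)) {
    populations <- rownames(mask) %||% sprintf("pop%02d", seq_len(nrow(mask)))
  }
  if (is.null(years)) {
    years <- colnames(mask) %||% seq_len(ncol(mask))
  }
  D <- as.matrix(D)
  stopifnot(nrow(D) == nrow(mask))
  vals <- matrix(NA_real_, nrow(mask), ncol(mask))

  # one Cholesky per distinct availability pattern
  key <- apply(mask, 2, function(m) paste(which(m), collapse = ","))
  for (kk in unique(key[colSums(mask) > 0])) {
    cols <- which(key == kk & colSums(mask) > 0)
    idx <- which(mask[, cols[1]])
    Rt <- t(chol_with_ridge(build_sigma(p, D[idx, idx, drop = FALSE])))
    z <- matrix(stats::rnorm(length(idx) * length(cols)), length(idx))
    vals[idx, cols] <- Rt %*% z
  }
  trait_panel(name, populations, as.integer(years), vals, mask)
}

chol_with_ridge <- function(sigma, ridge = 1e-8) {
  tryCatch(chol(sigma), error = function(e) {
    warning("singular model covariance: ridge ", ridge, " added",
            call. = FALSE)
    chol(sigma + diag(ridge, nrow(sigma)))
  })
}

#' Parametric bootstrap for synchrony parameters
#'
#' Simulates `B` datasets from the fitted synchrony model (via
#' [simulate_mvn_panel()], reusing the observed annual availability sets),
#' refits each with [fit_synchrony()], and summarizes the replicate
#' estimates by their median and 2.5/97.5 percentiles. All randomness
#' derives from `seed` through one documented split: replicate `b` uses
#' the `b`-th of `B` sub-seeds drawn once from `seed`, both for the data
#' simulation and for its multi-start design, so results are reproducible
#' and independent of evaluation order. Replicates whose refit fails are
#' dropped and counted; more than `max_fail` failures is an error.
#'
#' @param point Fitted [synchrony_params()] used as the simulation truth.
#' @param mask Availability matrix of the observed panel.
#' @param D Distance matrix in km.
#' @param B Number of bootstrap replicates (the full analysis uses 2000).
#' @param seed Integer master seed.
#' @param starts,l_max Passed to [fit_synchrony()].
#' @param max_fail Maximum tolerated fraction of non-converged replicates
#'   (default 0.2).
#' @return An object of class `synchrony_fit`: list with `point`,
#'   `replicates` (converged B x 3 matrix), `median`
#'   ([synchrony_params()]), `ci95` (2 x 3 matrix), `n_requested`,
#'   `n_converged`.
#' @export
parametric_bootstrap <- function(point, mask, D, B = 2000, seed = 1L,
                                 starts = 10, l_max = NULL, max_fail = 0.2) {
  validate_params(point)
  stopifnot(B >= 1)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, B))
  reps <- matrix(NA_real_, B, 3,
                 dimnames = list(NULL, c("rho0", "rho_inf", "l")))
  for (b in seq_len(B)) {
    sim <- withr::with_seed(rep_seeds[b],
                            simulate_mvn_panel(point, mask, D))
    fit <- tryCatch(
      fit_synchrony(sim, D, starts = starts, l_max = l_max,
                    start_seed = rep_seeds[b]),
      error = function(e) NULL)
    if (!is.null(fit)) reps[b, ] <- as.numeric(fit$params)
  }
  ok <- stats::complete.cases(reps)
  if (mean(!ok) > max_fail) {
    stop(sprintf("parametric bootstrap: %d of %d replicates failed to converge",
                 sum(!ok), B))
  }
  reps <- reps[ok, , drop = FALSE]
  med <- apply(reps, 2, stats::median)
  ci <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975))
  structure(
    list(point = point,
         replicates = reps,
         median = synchrony_params(med[1], med[2], med[3]),
         ci95 = ci,
         n_requested = B,
         n_converged = sum(ok)),
    class = "synchrony_fit")
}

#' @export
print.synchrony_fit <- function(x, ...) {
  cat("Synchrony fit (parametric bootstrap, ", x$n_converged, "/",
      x$n_requested, " replicates)\n", sep = "")
  m <- rbind(point = as.numeric(x$point),
             median = as.numeric(x$median),
             x$ci95)
  colnames(m) <- c("rho0", "rho_inf", "l_km")
  print(round(m, 3))
  invisible(x)
}

#' Fit synchrony and bootstrap its uncertainty in one call
#'
#' @inheritParams fit_synchrony
#' @inheritParams parametric_bootstrap
#' @return A `synchrony_fit` (see [parametric_bootstrap()]) with the extra
#'   elements `loglik`, `n_populations`, `n_years`.
#' @export
fit_synchrony_boot <- function(panel, D, B = 2000, seed = 1L, starts = 10,
                               l_max = NULL) {
  fit <- fit_synchrony(panel, D, starts = starts, l_max = l_max)
  out <- parametric_bootstrap(fit$params, panel$mask, D, B = B, seed = seed,
                              starts = starts, l_max = l_max)
  out$loglik <- fit$loglik
  out$n_populations <- length(panel$populations)
  out$n_years <- sum(colSums(panel$mask) > 0)
  out
}

#' Fitted correlogram curve with bootstrap band
#'
#' Evaluates the fitted correlation-by-distance curve on a distance grid:
#' the median and the 2.5/97.5 percentile envelope across bootstrap
#' replicates.
#'
#' @param fit A `synchrony_fit` from [parametric_bootstrap()] or
#'   [fit_synchrony_boot()].
#' @param distances Numeric grid of distances in km.
#' @return Tibble with columns `distance_km`,
#'   `fitted_correlation_median`, `ci_low`, `ci_high`.
#' @export
correlogram_curve <- function(fit, distances = seq(0, 2000, by = 25)) {
  stopifnot(inherits(fit, "synchrony_fit"))
  curves <- apply(fit$replicates, 1, function(r)
    correlation_at_distance(synchrony_params(r[1], r[2], r[3]), distances))
  curves <- matrix(curves, nrow = length(distances))
  tibble::tibble(
    distance_km = distances,
    fitted_correlation_median = apply(curves, 1, stats::median),
    ci_low = apply(curves, 1, stats::quantile, probs = 0.025),
    ci_high = apply(curves, 1, stats::quantile, probs = 0.975)
  )
}
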