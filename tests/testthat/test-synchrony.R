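test_that("the Gaussian correlogram interpolates between rho0 and rho_inf", {
  p <- synchrony_params(0.800, 0.263, 247)
  expect_equal(correlation_at_distance(p, 0), 0.800)
  expect_equal(correlation_at_distance(p, 1e9), 0.263, tolerance = 1e-12)
  # direct evaluation at d = l: rho_inf + (rho0 - rho_inf) e^(-1/2)
  expect_equal(correlation_at_distance(p, 247),
               0.263 + 0.537 * exp(-0.5), tolerance = 1e-12)

  # bounds and monotone decay on a grid, for several parameter draws
  for (seed in 1:20) {
    pp <- withr::with_seed(seed, {
      r0 <- runif(1); synchrony_params(r0, runif(1, 0, r0), runif(1, 1, 3000))
    })
    rho <- correlation_at_distance(pp, seq(0, 5000, by = 10))
    expect_true(all(rho <= pp$rho0 + 1e-12 & rho >= pp$rho_inf - 1e-12))
    expect_true(all(diff(rho) <= 1e-12))
  }
  expect_error(correlation_at_distance(p, -1), "non-negative")
  expect_error(synchrony_params(0.5, 0.6, 100), "rho_inf")
  expect_error(synchrony_params(1.2, 0.1, 100), "rho0")
  expect_error(synchrony_params(0.5, 0.1, 0), "positive")
})

test_that("model correlation matrices have unit diagonal, the nugget, and are PSD", {
  p <- synchrony_params(0.8, 0.2, 300)
  expect_identical(build_sigma(p, matrix(0, 1, 1)), matrix(1, 1, 1))
  # co-located sites keep the nugget: off-diagonal rho0, not 1
  s2 <- build_sigma(p, tiny_D(0))
  expect_equal(diag(s2), c(p1 = 1, p2 = 1))
  expect_equal(s2[1, 2], 0.8)

  # PSD across 100 randomized valid (params, layout) draws
  for (seed in 1:100) {
    ev <- withr::with_seed(seed, {
      n <- sample(3:25, 1)
      xy <- matrix(runif(2 * n, 0, 3000), n, 2)
      r0 <- runif(1)
      pp <- synchrony_params(r0, runif(1, 0, r0), runif(1, 5, 5000))
      min(eigen(build_sigma(pp, as.matrix(dist(xy))),
                symmetric = TRUE, only.values = TRUE)$values)
    })
    expect_gte(ev, -1e-10)
  }
})

test_that("the annual MVN log-likelihood matches closed forms and a dense-matrix oracle", {
  p <- synchrony_params(0.8, 0.0, 300)
  # one population, value 0: standard normal at 0
  expect_equal(total_loglik(p, tiny_panel(matrix(0, 1, 1)), matrix(0, 1, 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  # two very distant populations, rho_inf = 0: independent standard normals
  expect_equal(total_loglik(p, tiny_panel(matrix(0, 2, 1)), tiny_D(1e8)),
               -log(2 * pi), tolerance = 1e-12)
  # implied correlation 0.5 at any distance, values (1, 1): closed form
  p5 <- synchrony_params(0.5, 0.5, 100)
  expect_equal(total_loglik(p5, tiny_panel(matrix(1, 2, 1)), tiny_D(500)),
               -log(2 * pi) - 0.5 * log(0.75) - 0.5 * (4 / 3),
               tolerance = 1e-12)

  # oracle equivalence on dimensions 1-5, complete and incomplete panels
  for (k in 1:5) {
    cmp <- withr::with_seed(100 + k, {
      xy <- matrix(runif(2 * k, 0, 1500), k, 2)
      D <- as.matrix(dist(xy))
      vals <- matrix(rnorm(k * 6), k, 6)
      if (k >= 3) vals[1, 2] <- vals[k, 5] <- NA  # varying availability
      panel <- tiny_panel(vals)
      pp <- synchrony_params(0.7, 0.15, 400)
      sig <- build_sigma(pp, D)
      oracle <- sum(vapply(seq_len(ncol(vals)), function(t) {
        obs <- which(!is.na(vals[, t]))
        dense_mvn_loglik(vals[obs, t], sig[obs, obs, drop = FALSE])
      }, numeric(1)))
      c(total_loglik(pp, panel, D), oracle)
    })
    expect_equal(cmp[1], cmp[2], tolerance = 1e-8)
  }
})

test_that("the log-likelihood is invariant to population reordering and additive over years", {
  d <- sim_truth_panel(5, n_sites = 8, n_years = 12,
                       truth = synchrony_params(0.7, 0.1, 500))
  p <- synchrony_params(0.6, 0.05, 600)
  ll <- total_loglik(p, d$panel, d$D)

  perm <- withr::with_seed(6, sample(8))
  panel_p <- panel_subset(d$panel, d$panel$populations[perm])
  ll_p <- total_loglik(p, panel_p, d$D[perm, perm])
  expect_equal(ll_p, ll, tolerance = 1e-10)

  # duplicating every year doubles the total at fixed parameters
  dbl <- trait_panel("toy", d$panel$populations,
                     c(d$panel$years, d$panel$years + 100L),
                     cbind(d$panel$values, d$panel$values))
  expect_equal(total_loglik(p, dbl, d$D), 2 * ll, tolerance = 1e-10)

  # misaligned population order is caught
  Dbad <- d$D[perm, perm]
  expect_error(total_loglik(p, d$panel, Dbad), "order")
})

test_that("fitting recovers the independence limit and is permutation invariant", {
  # i.i.d. noise across distant sites: rho0 near 0, loglik within 2 units
  # of the independent-normals loglik
  vals <- withr::with_seed(42, matrix(rnorm(30 * 50), 30, 50))
  vals <- t(apply(vals, 1, function(r) (r - mean(r)) / sd(r)))
  panel <- tiny_panel(vals)
  layout <- generate_sites(30, c(4000, 4000), seed = 9)
  fit <- fit_synchrony(panel, unname(layout$D))
  ll_indep <- sum(dnorm(vals, log = TRUE))
  # fitted correlation at every observed distance is near zero (rho0 alone
  # is not identified when l collapses below the smallest pair distance)
  d_min <- min(layout$D[upper.tri(layout$D)])
  expect_lt(correlation_at_distance(fit$params, d_min), 0.1)
  expect_gte(fit$loglik, ll_indep - 1e-6)   # independence is nested
  expect_lt(fit$loglik - ll_indep, 2)

  # simultaneous reordering of panel and D leaves the fit unchanged
  d <- sim_truth_panel(21, n_sites = 10, n_years = 25,
                       truth = synchrony_params(0.7, 0.1, 500))
  f1 <- fit_synchrony(d$panel, d$D)
  perm <- withr::with_seed(3, sample(10))
  f2 <- fit_synchrony(panel_subset(d$panel, d$panel$populations[perm]),
                      d$D[perm, perm])
  expect_equal(as.numeric(f1$params), as.numeric(f2$params), tolerance = 1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)

  expect_error(fit_synchrony(tiny_panel(matrix(0, 1, 5)), matrix(0, 1, 1)),
               "at least 2 populations")
})

test_that("pairwise empirical correlations report distance, r and overlap", {
  # two identical overlapping series -> r = 1; anti-correlated -> -1
  vals <- rbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))
  panel <- tiny_panel(vals)
  pw <- pairwise_empirical_correlations(panel, tiny_D(100, 200, 150),
                                        min_overlap = 3)
  expect_equal(nrow(pw), 3)
  r12 <- pw$pearson_r[pw$pop_a == "p1" & pw$pop_b == "p2"]
  r13 <- pw$pearson_r[pw$pop_a == "p1" & pw$pop_b == "p3"]
  expect_equal(r12, 1)
  expect_equal(r13, -1)
  expect_equal(pw$distance_km[pw$pop_a == "p1" & pw$pop_b == "p2"], 100)
  expect_equal(pw$n_overlap, rep(5L, 3))

  # pairs below min_overlap are absent
  vals2 <- vals
  vals2[2, 5] <- NA
  pw5 <- pairwise_empirical_correlations(tiny_panel(vals2),
                                         tiny_D(100, 200, 150),
                                         min_overlap = 5)
  expect_false(any(pw5$pop_a == "p1" & pw5$pop_b == "p2"))
  expect_true(any(pw5$pop_a == "p1" & pw5$pop_b == "p3"))

  # constant overlap series skipped with a warning
  vals3 <- rbind(c(1, 1, 1, 1, 1), c(1, 2, 3, 4, 5))
  expect_warning(
    pw3 <- pairwise_empirical_correlations(tiny_panel(vals3), tiny_D(100),
                                           min_overlap = 3),
    "constant")
  expect_equal(nrow(pw3), 0)
  expect_error(pairwise_empirical_correlations(panel, tiny_D(1, 2, 3),
                                               min_overlap = 2), ">= 3")
})
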