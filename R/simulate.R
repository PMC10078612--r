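#' Simulation scenario with known synchrony structure
#'
#' Bundles everything needed to generate a synthetic study: a site layout,
#' a latent synchronous field with Gaussian-correlogram truth, per-
#' population means, linear time trends and trait SDs, optional
#' missingness, and an optional spatially autocorrelated climate driver
#' with population-specific slopes. Defaults emulate a multi-decade
#' nest-box monitoring scheme: a few dozen populations spread over a
#' region some thousands of km across, observed for decades with partly
#' overlapping coverage.
#'
#' @param n_sites Number of populations (default 30).
#' @param region Either a numeric `c(width_km, height_km)` planar region
#'   (Euclidean distances; the default `c(2000, 2000)`), or a list
#'   `list(lat = c(min, max), lon = c(min, max))` for a geographic box
#'   (great-circle distances).
#' @param n_years Number of calendar years (default 40, starting 1980).
#' @param first_year First calendar year.
#' @param truth [synchrony_params()] of the latent trait field.
#' @param mean_value Per-population long-term mean, recycled (trait units).
#' @param trend_per_year Per-population linear trend, recycled (trait
#'   units per year).
#' @param trait_sd Per-population SD of the synchronous fluctuation,
#'   recycled, `> 0`.
#' @param missing_rate Independent probability that an observed
#'   population-year is thinned out, in `[0, 1)`.
#' @param block_missing Optional 2-column matrix or data frame
#'   (`first_year`, `last_year`) per population: observations outside the
#'   window are masked, emulating schemes that started late or ended
#'   early.
#' @param climate Optional list with elements `truth_c`
#'   ([synchrony_params()] of the climate field), `beta` (per-population
#'   slope, recycled, trait units per climate SD) and `noise_truth`
#'   ([synchrony_params()] of the residual trait field). When set, the
#'   trait is `mean + trend + beta * C + trait_sd * e`.
#' @param seed Integer seed; generation is deterministic given the
#'   scenario.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_sites = 30, region = c(2000, 2000),
                                n_years = 40, first_year = 1980,
                                truth = synchrony_params(0.7, 0.1, 500),
                                mean_value = 0, trend_per_year = 0,
                                trait_sd = 1, missing_rate = 0,
                                block_missing = NULL, climate = NULL,
                                seed = 1L) {
  stopifnot(n_sites >= 2, n_years >= 2, trait_sd > 0,
            missing_rate >= 0, missing_rate < 1)
  validate_params(truth)
  if (!is.null(climate)) {
    stopifnot(all(c("truth_c", "beta", "noise_truth") %in% names(climate)))
    validate_params(climate$truth_c)
    validate_params(climate$noise_truth)
  }
  structure(
    list(n_sites = n_sites, region = region, n_years = n_years,
         first_year = first_year, truth = truth,
         mean_value = rep_len(mean_value, n_sites),
         trend_per_year = rep_len(trend_per_year, n_sites),
         trait_sd = rep_len(trait_sd, n_sites),
         missing_rate = missing_rate, block_missing = block_missing,
         climate = climate, seed = as.integer(seed)),
    class = "simulation_scenario")
}

#' Generate a random site layout and its distance matrix
#'
#' Sites are placed uniformly at random in the region. Planar regions use
#' Euclidean distances in km; lat/lon boxes use great-circle distances.
#'
#' @param n Number of sites (`>= 2`).
#' @param region See [simulation_scenario()].
#' @param seed Integer seed (deterministic layouts).
#' @return List with `sites` (tibble: `population_id` plus either
#'   `x_km`/`y_km` or `latitude`/`longitude`) and `D` (distance matrix in
#'   km from [distance_matrix()]).
#' @export
generate_sites <- function(n, region = c(2000, 2000), seed = 1L) {
  stopifnot(n >= 2)
  ids <- sprintf("pop%02d", seq_len(n))
  if (is.numeric(region) && length(region) == 2) {
    if (all(region <= 0)) stop("degenerate region: no positive extent")
    sites <- withr::with_seed(seed, tibble::tibble(
      population_id = ids,
      x_km = stats::runif(n, 0, region[1]),
      y_km = stats::runif(n, 0, region[2])))
  } else if (is.list(region) && all(c("lat", "lon") %in% names(region))) {
    if (diff(region$lat) <= 0 && diff(region$lon) <= 0) {
      stop("degenerate region: empty lat/lon box")
    }
    sites <- withr::with_seed(seed, tibble::tibble(
      population_id = ids,
      latitude = stats::runif(n, region$lat[1], region$lat[2]),
      longitude = stats::runif(n, region$lon[1], region$lon[2])))
  } else {
    stop("region must be c(width_km, height_km) or list(lat=, lon=)")
  }
  list(sites = sites, D = distance_matrix(sites))
}

#' Generate trait (and optional climate) panels from a scenario
#'
#' The latent field `z` is drawn year by year from the multivariate normal
#' distribution with correlation matrix [build_sigma()] at the scenario
#' truth; years are independent and identically distributed, matching the
#' model's assumption for detrended series. The observable raw panel adds
#' per-population mean, linear trend (centred on the middle year) and
#' scale, and optionally a climate term `beta * C` with its own
#' spatially autocorrelated fields `C` and residual `e`. Missingness
#' (independent thinning plus per-population year windows) is applied to
#' the raw panel only; the latent field is returned complete so tests can
#' compare against the exact generating values.
#'
#' @param scenario A [simulation_scenario()].
#' @return List with `sites`, `D`, `raw` ([trait_panel()] with
#'   missingness), `latent` (complete unit-variance synchronous field: `z`
#'   without a climate driver, the residual field `e` with one), and
#'   `climate` (a [climate_panel()], or `NULL`).
#' @export
generate_panel <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  layout <- generate_sites(sc$n_sites, sc$region, seed = sc$seed)
  years <- sc$first_year + seq_len(sc$n_years) - 1L
  full <- matrix(TRUE, sc$n_sites, sc$n_years)

  out <- withr::with_seed(sc$seed + 1L, {
    climate_panel_obj <- NULL
    if (is.null(sc$climate)) {
      z <- simulate_mvn_panel(sc$truth, full, layout$D, years = years,
                              populations = layout$sites$population_id,
                              name = "latent")
      synced <- sc$trait_sd * z$values
    } else {
      cfield <- simulate_mvn_panel(sc$climate$truth_c, full, layout$D,
                                   years = years,
                                   populations = layout$sites$population_id,
                                   name = "climate")
      z <- simulate_mvn_panel(sc$climate$noise_truth, full, layout$D,
                              years = years,
                              populations = layout$sites$population_id,
                              name = "latent")
      beta <- rep_len(sc$climate$beta, sc$n_sites)
      synced <- beta * cfield$values + sc$trait_sd * z$values
      climate_panel_obj <- climate_panel("climate",
                                         layout$sites$population_id, years,
                                         cfield$values)
    }
    trend <- outer(sc$trend_per_year, years - stats::median(years))
    raw_vals <- sc$mean_value + trend + synced

    mask <- full
    if (sc$missing_rate > 0) {
      mask <- mask & matrix(stats::runif(length(mask)) >= sc$missing_rate,
                            nrow(mask))
    }
    if (!is.null(sc$block_missing)) {
      bm <- as.matrix(sc$block_missing)
      stopifnot(nrow(bm) == sc$n_sites, ncol(bm) == 2)
      for (i in seq_len(sc$n_sites)) {
        mask[i, years < bm[i, 1] | years > bm[i, 2]] <- FALSE
      }
    }
    if (sum(colSums(mask) >= 2) < 2) {
      stop("missingness pattern leaves fewer than 2 years with 2+ sites")
    }
    raw_vals[!mask] <- NA_real_
    list(raw = trait_panel("simulated_trait",
                           layout$sites$population_id, years, raw_vals, mask),
         latent = z, climate = climate_panel_obj)
  })
  c(list(sites = layout$sites, D = layout$D), out)
}

#' Emit a minimal brood table around annual panel values
#'
#' Expands each observed population-year of a panel into `n_broods`
#' individual brood records scattered around the annual value, so that the
#' record-level filtering and aggregation steps can be exercised on
#' synthetic data. Values are rounded to integers for count-like traits.
#' This is deliberately minimal: it does not model within-season
#' laying-date skew or brood-level covariance.
#'
#' @param panel A [trait_panel()] of annual average values.
#' @param trait Which trait column the values populate.
#' @param n_broods Broods per population-year (default 8).
#' @param within_sd Within-year SD of brood values around the annual value.
#' @param seed Integer seed.
#' @return A tibble of brood records (see [filter_broods()] for columns),
#'   all first clutches, none experimental.
#' @export
simulate_broods <- function(panel, trait = "laying_date", n_broods = 8,
                            within_sd = 2, seed = 1L) {
  trait <- match.arg(trait, TRAIT_NAMES[1:3])
  long <- panel_to_long(panel)
  withr::with_seed(seed, {
    n <- nrow(long) * n_broods
    df <- tibble::tibble(
      population_id = rep(long$population_id, each = n_broods),
      year = rep(long$year, each = n_broods),
      laying_date = NA_real_, clutch_size = NA_real_,
      fledgling_number = NA_real_,
      is_first_clutch = TRUE, is_experimental = FALSE)
    vals <- rep(long$value, each = n_broods) + stats::rnorm(n, 0, within_sd)
    if (trait == "laying_date") {
      df$laying_date <- round(vals)
    } else if (trait == "clutch_size") {
      df$clutch_size <- pmax(1, round(vals))
    } else {
      df$clutch_size <- pmax(1, round(vals)) + 2
      df$fledgling_number <- pmax(0, pmin(round(vals), df$clutch_size))
    }
    df
  })
}
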