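#!/usr/bin/env Rscript
# Full pipeline on the synthetic study: filter broods, aggregate annual
# median laying dates, detrend + normalize, fit the Gaussian correlogram
# with parametric bootstrap, and measure how much of the synchrony the
# spring-temperature field accounts for.
#
# Run analysis/01_simulate_study.R first.

library(traitsync)

inp <- file.path("results", "synthetic_study")
stopifnot(file.exists(file.path(inp, "broods.csv")))

cfg <- pipeline_config(
  broods = file.path(inp, "broods.csv"),
  sites = file.path(inp, "sites.csv"),
  climate = c(mean_temperature = file.path(inp, "climate_mean_temperature.csv")),
  climate_daily = FALSE,           # the generator emits annual Feb-May means
  traits = "laying_date",
  # every simulated population shares the same laying-date trend while the
  # climate field is trend-free; a climate-only regression would leave that
  # shared trend in the residuals and mask the climate contribution, so the
  # regressions here include the year term
  climate_include_year = TRUE,
  min_years = 9, B = 200, starts = 10, seed = 106L,
  out_dir = file.path("results", "synthetic_study", "fits"))

res <- run_pipeline(cfg)
stopifnot(res$status == 0L)

fit <- jsonlite::read_json(file.path(cfg$out_dir,
                                     "fit_synthetic tit_laying_date.json"))
cmp <- jsonlite::read_json(file.path(
  cfg$out_dir, "comparison_synthetic tit_laying_date_mean_temperature.json"))

cat(sprintf(
  "laying-date synchrony (%d populations): rho0 = %.3f [%.3f, %.3f], rho_inf = %.3f, l = %.0f km\n",
  fit$n_populations, fit$bootstrap$median$rho0,
  fit$bootstrap$ci95$rho0[[1]], fit$bootstrap$ci95$rho0[[2]],
  fit$bootstrap$median$rho_inf, fit$bootstrap$median$l_km))
cat(sprintf(
  "after temperature adjustment:  rho0 = %.3f; synchrony removed: %.3f at 0 km, %.3f at 1000 km\n",
  cmp$adjusted$bootstrap$median$rho0, cmp$delta_at$`0_km`,
  cmp$delta_at$`1000_km`))
cat("the removal is largest at long range, where the broad-scale climate field\n",
    "dominates the correlogram; the short-range residual synchrony remains\n", sep = "")
cat("artifacts in", cfg$out_dir, "\n")
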