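#' Pipeline configuration
#'
#' Collects input paths, analysis choices and thresholds for a full
#' end-to-end run: brood filtering, annual aggregation, detrending,
#' synchrony fitting with parametric bootstrap, and (optionally) climate
#' adjustment, executed per species x trait.
#'
#' @param broods Path to a brood CSV (see [read_broods()]).
#' @param sites Path to a sites CSV (see [read_sites()]).
#' @param climate Named character vector or list of climate CSV paths,
#'   e.g. `c(mean_temperature = "temp.csv")`; `NULL` disables climate
#'   adjustment.
#' @param climate_daily `TRUE` if climate files hold daily series to be
#'   collapsed with [seasonal_mean()]; `FALSE` for annual series.
#' @param traits Traits to analyse.
#' @param species Species to analyse (`NULL` = all present in sites CSV).
#' @param min_years Minimum observed years per population (default 9).
#' @param min_broods Minimum broods per population-year (default 2).
#' @param months Climate window months (default `2:5`, February-May).
#' @param min_latitude Optional latitude cutoff: populations south of it
#'   are excluded (a northern-subset robustness run).
#' @param climate_include_year Add a calendar-year term to the per-population
#'   climate regressions (see [residualize_on_climate()]). Matters when
#'   traits trend but the climate variable does not: with `FALSE` a shared
#'   trait trend stays in the residuals and re-synchronizes the adjusted
#'   panel.
#' @param B Bootstrap replicates (default 2000).
#' @param starts Multi-start count for each fit.
#' @param seed Master seed: every random draw in the run derives from it.
#' @param out_dir Output directory for the artifact tree.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(broods, sites, climate = NULL,
                            climate_daily = TRUE,
                            traits = c("laying_date", "clutch_size",
                                       "fledgling_number"),
                            species = NULL, min_years = 9, min_broods = 2,
                            months = 2:5, min_latitude = NULL,
                            climate_include_year = FALSE, B = 2000,
                            starts = 10, seed = 1L, out_dir = "results") {
  stopifnot(B >= 1, min_years >= 3, min_broods >= 1)
  traits <- match.arg(traits, TRAIT_NAMES, several.ok = TRUE)
  for (p in c(broods, sites, unlist(climate))) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  structure(
    list(broods = broods, sites = sites, climate = climate,
         climate_daily = climate_daily, traits = traits, species = species,
         min_years = min_years, min_broods = min_broods, months = months,
         min_latitude = min_latitude,
         climate_include_year = climate_include_year, B = B, starts = starts,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields above.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  y$climate <- if (!is.null(y$climate)) unlist(y$climate)
  if (!is.null(y$months)) y$months <- as.integer(y$months)
  do.call(pipeline_config, y)
}

#' Run the full synchrony pipeline
#'
#' For every species x trait cell: filter brood records, aggregate to an
#' annual panel, drop short series, detrend and normalize, fit the
#' synchrony model with parametric bootstrap, and write a fit JSON, a
#' correlogram CSV and a pairwise-correlation CSV. For every configured
#' climate variable, additionally write a before/after comparison JSON and
#' a figure. A manifest (config hash, seed, package version, per-cell
#' status) is written at the end; identical config + seed gives identical
#' outputs. A failing cell is logged and skipped; other cells continue.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `status` (0 = all cells ok, 1 = all
#'   failed, 2 = partial) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  broods <- read_broods(config$broods)
  sites <- read_sites(config$sites)
  if (!is.null(config$min_latitude)) {
    sites <- sites[sites$latitude >= config$min_latitude, , drop = FALSE]
  }
  species <- config$species %||%
    (if ("species" %in% names(sites)) unique(sites$species) else "all")

  climates <- list()
  for (nm in names(config$climate)) {
    cl <- read_climate(config$climate[[nm]], daily = config$climate_daily)
    climates[[nm]] <- if (config$climate_daily) {
      climate_panel_from_daily(cl, nm, months = config$months)
    } else {
      p <- panel_from_long(cl, name = nm)
      climate_panel(nm, p$populations, p$years, p$values, p$mask)
    }
  }

  cells <- expand.grid(species = species, trait = config$traits,
                       stringsAsFactors = FALSE)
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max - 1L,
                                       nrow(cells) * (1 + length(climates))))
  results <- list()
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; tr <- cells$trait[i]
    tag <- paste(sp, tr, sep = "_")
    t0 <- Sys.time()
    res <- tryCatch({
      sp_sites <- if ("species" %in% names(sites) && sp != "all") {
        sites[sites$species == sp, , drop = FALSE]
      } else sites
      sp_broods <- broods[broods$population_id %in% sp_sites$population_id, ,
                          drop = FALSE]
      filtered <- filter_broods(sp_broods, tr, min_broods = config$min_broods)
      panel <- annual_average(filtered, tr, min_broods = config$min_broods)
      panel <- drop_short_series(panel, config$min_years)
      sp_sites <- sp_sites[match(panel$populations, sp_sites$population_id), ,
                           drop = FALSE]
      D <- distance_matrix(sp_sites)
      write_panel_csv(panel, file.path(config$out_dir,
                                       paste0("panel_", tag, ".csv")))
      dn <- detrend_normalize(panel)
      write_panel_csv(dn, file.path(config$out_dir,
                                    paste0("panel_detrended_", tag, ".csv")))

      fit <- fit_synchrony_boot(dn, D, B = config$B, seed = seeds[i],
                                starts = config$starts)
      write_fit_json(fit, file.path(config$out_dir, paste0("fit_", tag, ".json")),
                     trait = tr, species = sp)
      grid <- seq(0, max(D), length.out = 81)
      readr::write_csv(correlogram_curve(fit, grid),
                       file.path(config$out_dir,
                                 paste0("correlogram_", tag, ".csv")))
      readr::write_csv(pairwise_empirical_correlations(dn, D),
                       file.path(config$out_dir, paste0("pairwise_", tag, ".csv")))

      for (ci in seq_along(climates)) {
        nm <- names(climates)[ci]
        cmp <- compare_synchrony(
          dn, climates[[nm]], D, B = config$B,
          seed = seeds[nrow(cells) * ci + i], raw_source = panel,
          distances = seq(0, max(D), length.out = 81),
          include_year = config$climate_include_year,
          starts = config$starts)
        jsonlite::write_json(comparison_report(cmp),
                             file.path(config$out_dir,
                                       paste0("comparison_", tag, "_", nm, ".json")),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             na = "null")
        ggplot2::ggsave(
          file.path(config$out_dir, paste0("comparison_", tag, "_", nm, ".pdf")),
          plot_synchrony_comparison(cmp), width = 7, height = 5)
      }
      list(status = "ok", n_populations = length(panel$populations))
    }, error = function(e) {
      message(sprintf("[pipeline] species=%s trait=%s failed: %s",
                      sp, tr, conditionMessage(e)))
      list(status = "error", message = conditionMessage(e))
    })
    res$elapsed_s <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    message(sprintf("[pipeline] species=%s trait=%s status=%s elapsed=%.1fs",
                    sp, tr, res$status, res$elapsed_s))
    results[[tag]] <- res
  }

  ok <- vapply(results, function(r) identical(r$status, "ok"), logical(1))
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("traitsync")),
    r_version = as.character(getRversion()),
    cells = results)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  status <- if (all(ok)) 0L else if (any(ok)) 2L else 1L
  invisible(list(status = status, manifest = manifest))
}
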