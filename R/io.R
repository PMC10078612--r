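#' Read and write the pipeline's file formats
#'
#' All files are comma-separated UTF-8 with a header row, ISO-8601 dates
#' and `.` decimal separator; empty fields are missing values.
#'
#' * Brood CSV: `population_id, species, year, laying_date, clutch_size,
#'   fledgling_number, is_first_clutch, is_experimental`.
#' * Sites CSV: `population_id, species, latitude, longitude`.
#' * Climate CSV, daily: `population_id, date, value`; annual:
#'   `population_id, year, value`.
#' * Panel CSV (intermediate/output): `population_id, year, value`.
#'
#' @param path File path.
#' @return A tibble (readers) or the input, invisibly (writers).
#' @name traitsync_io
NULL

csv_cols <- function(...) readr::cols(...)

#' @rdname traitsync_io
#' @export
read_broods <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = csv_cols(
    population_id = readr::col_character(),
    year = readr::col_integer(),
    laying_date = readr::col_double(),
    clutch_size = readr::col_double(),
    fledgling_number = readr::col_double(),
    is_first_clutch = readr::col_logical(),
    is_experimental = readr::col_logical(),
    .default = readr::col_guess()))
  validate_broods(df)
  df
}

#' @rdname traitsync_io
#' @export
read_sites <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, col_types = csv_cols(
    population_id = readr::col_character(),
    .default = readr::col_guess()))
  if (anyDuplicated(df$population_id)) stop("duplicated population_id in ", path)
  df
}

#' @rdname traitsync_io
#' @param daily If `TRUE`, expect a daily series (`date` column), else an
#'   annual one (`year` column).
#' @export
read_climate <- function(path, daily = TRUE) {
  if (daily) {
    readr::read_csv(path, show_col_types = FALSE, col_types = csv_cols(
      population_id = readr::col_character(),
      date = readr::col_date(),
      value = readr::col_double()))
  } else {
    readr::read_csv(path, show_col_types = FALSE, col_types = csv_cols(
      population_id = readr::col_character(),
      year = readr::col_integer(),
      value = readr::col_double()))
  }
}

#' @rdname traitsync_io
#' @param panel A [trait_panel()].
#' @export
write_panel_csv <- function(panel, path) {
  readr::write_csv(panel_to_long(panel), path)
  invisible(panel)
}

#' @rdname traitsync_io
#' @param name Panel name used when reading back.
#' @export
read_panel_csv <- function(path, name = "trait") {
  panel_from_long(readr::read_csv(path, show_col_types = FALSE,
                                  col_types = csv_cols(
                                    population_id = readr::col_character(),
                                    year = readr::col_integer(),
                                    value = readr::col_double())),
                  name = name)
}

#' Fit report as a JSON-ready list
#'
#' @param fit A `synchrony_fit` from [fit_synchrony_boot()].
#' @param trait,species Labels recorded in the report.
#' @return A named list mirroring the JSON structure.
#' @export
fit_report <- function(fit, trait = NA_character_, species = NA_character_) {
  stopifnot(inherits(fit, "synchrony_fit"))
  list(
    trait = trait, species = species,
    n_populations = fit$n_populations %||% NA_integer_,
    n_years = fit$n_years %||% NA_integer_,
    point = list(rho0 = fit$point$rho0, rho_inf = fit$point$rho_inf,
                 l_km = fit$point$l),
    loglik = fit$loglik %||% NA_real_,
    bootstrap = list(
      B = fit$n_requested, converged = fit$n_converged,
      median = list(rho0 = fit$median$rho0, rho_inf = fit$median$rho_inf,
                    l_km = fit$median$l),
      ci95 = list(rho0 = unname(fit$ci95[, "rho0"]),
                  rho_inf = unname(fit$ci95[, "rho_inf"]),
                  l_km = unname(fit$ci95[, "l"]))))
}

#' @rdname fit_report
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path, trait = NA_character_,
                           species = NA_character_) {
  jsonlite::write_json(fit_report(fit, trait, species), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(fit)
}

#' Comparison report as a JSON-ready list
#'
#' @param cmp A `synchrony_comparison` from [compare_synchrony()].
#' @param delta_at Distances (km) at which the median synchrony drop is
#'   reported.
#' @return A named list mirroring the JSON structure.
#' @export
comparison_report <- function(cmp, delta_at = c(0, 500, 1000, 2000)) {
  stopifnot(inherits(cmp, "synchrony_comparison"))
  med <- function(fit, d) {
    reps <- fit$replicates
    stats::median(apply(reps, 1, function(r)
      correlation_at_distance(synchrony_params(r[1], r[2], r[3]), d)))
  }
  deltas <- lapply(delta_at, function(d)
    med(cmp$raw_fit, d) - med(cmp$adjusted_fit, d))
  names(deltas) <- paste0(delta_at, "_km")
  list(climate_variable = cmp$climate_variable,
       raw = fit_report(cmp$raw_fit),
       adjusted = fit_report(cmp$adjusted_fit),
       delta_at = deltas)
}
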