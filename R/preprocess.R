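#' Filter brood records for a trait analysis
#'
#' Applies the standard inclusion rules for nest-box brood data before
#' annual aggregation: only first clutches, only broods not subjected to
#' experiments, records missing the target trait dropped, and — for the
#' fledgling traits only — broods with at least one fledgling, so that
#' fledgling number reflects parental effort rather than complete brood
#' loss (predation etc.). After these row-level rules, population-years
#' left with fewer than `min_broods` broods are dropped entirely.
#'
#' @param records Data frame of brood records with columns
#'   `population_id`, `year`, `laying_date`, `clutch_size`,
#'   `fledgling_number`, `is_first_clutch`, `is_experimental`. Missing
#'   trait values are `NA`.
#' @param trait Target trait: one of `"laying_date"`, `"clutch_size"`,
#'   `"fledgling_number"`, `"fledgling_success"`. The at-least-one-fledgling
#'   rule applies only to the two fledgling traits.
#' @param min_broods Minimum broods per population-year (default 2).
#' @return The filtered records, input row order preserved. An empty
#'   result is returned as a zero-row data frame, not an error.
#' @export
filter_broods <- function(records, trait, min_broods = 2) {
  trait <- match.arg(trait, TRAIT_NAMES)
  if (nrow(records) == 0) stop("no brood records supplied")
  validate_broods(records)

  keep <- records$is_first_clutch & !records$is_experimental
  keep <- keep & switch(trait,
    laying_date = !is.na(records$laying_date),
    clutch_size = !is.na(records$clutch_size),
    fledgling_number = !is.na(records$fledgling_number),
    fledgling_success = !is.na(records$fledgling_number) &
      !is.na(records$clutch_size)
  )
  if (trait %in% c("fledgling_number", "fledgling_success")) {
    keep <- keep & !is.na(records$fledgling_number) &
      records$fledgling_number >= 1
  }
  out <- records[which(keep), , drop = FALSE]
  # re-apply the broods-per-year rule after the row-level exclusions
  py <- paste(out$population_id, out$year, sep = "\r")
  out <- out[py %in% names(which(table(py) >= min_broods)), , drop = FALSE]
  out
}

validate_broods <- function(records) {
  req <- c("population_id", "year", "laying_date", "clutch_size",
           "fledgling_number", "is_first_clutch", "is_experimental")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("brood records missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(records$year < 1900 | records$year > 2100, na.rm = TRUE)) {
    stop("brood year outside [1900, 2100]")
  }
  both <- !is.na(records$fledgling_number) & !is.na(records$clutch_size)
  bad <- which(both & records$fledgling_number > records$clutch_size)
  if (length(bad)) {
    stop("fledgling_number exceeds clutch_size for record(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (population ", records$population_id[bad[1]],
         ", year ", records$year[bad[1]], ")")
  }
  neg <- function(x) any(!is.na(x) & x < 0)
  if (neg(records$clutch_size) || neg(records$fledgling_number)) {
    stop("negative clutch_size or fledgling_number")
  }
  invisible(records)
}

#' Aggregate brood records into an annual trait panel
#'
#' Laying date (days, 1 = April 1) is aggregated by the annual median,
#' because within-year laying-date distributions are typically
#' right-skewed; clutch size and fledgling number by the arithmetic mean;
#' fledgling success by the mean of per-brood `fledgling_number /
#' clutch_size`. Even-count medians are the mean of the two middle values,
#' so non-integer medians are allowed.
#'
#' @param records Brood records, already passed through [filter_broods()]
#'   for the same trait.
#' @param trait Trait name (see [filter_broods()]).
#' @param min_broods Population-years with fewer broods than this are
#'   masked out (default 2, matching the filter).
#' @return A [trait_panel()] spanning the populations and years present.
#' @export
annual_average <- function(records, trait, min_broods = 2) {
  trait <- match.arg(trait, TRAIT_NAMES)
  if (nrow(records) == 0) stop("no brood records to aggregate")
  validate_broods(records)

  x <- switch(trait,
    laying_date = records$laying_date,
    clutch_size = records$clutch_size,
    fledgling_number = records$fledgling_number,
    fledgling_success = {
      if (any(!is.na(records$clutch_size) & records$clutch_size == 0 &
                !is.na(records$fledgling_number))) {
        stop("fledgling_success undefined for clutch_size 0")
      }
      records$fledgling_number / records$clutch_size
    })
  agg_fun <- if (trait == "laying_date") stats::median else mean

  df <- tibble::tibble(population_id = as.character(records$population_id),
                       year = as.integer(records$year), x = x)
  df <- df[!is.na(df$x), , drop = FALSE]
  ann <- df |>
    dplyr::summarise(value = agg_fun(.data$x), n_broods = dplyr::n(),
                     .by = c("population_id", "year")) |>
    dplyr::filter(.data$n_broods >= min_broods)
  if (nrow(ann) == 0) stop("no population-year reaches ", min_broods, " broods")
  panel_from_long(ann, name = trait)
}

#' Seasonal-window mean of a daily climate series
#'
#' Collapses a daily series to one value per year: the mean over a window
#' of calendar months (default February-May, the period before and during
#' breeding for European hole-nesting passerines). Years where more than
#' `max_missing` of the window's calendar days are absent from the input
#' are dropped; the window length is 120 days (121 in leap years, Feb 29
#' included) for the default months.
#'
#' @param daily Data frame with columns `date` (`Date` or ISO-8601 text)
#'   and `value`.
#' @param months Integer months defining the window (default `2:5`).
#' @param max_missing Maximum tolerated fraction of missing window days
#'   (default 0.1).
#' @return A tibble with columns `year`, `value`, `n_days`, `n_expected`,
#'   one row per retained year.
#' @export
seasonal_mean <- function(daily, months = 2:5, max_missing = 0.1) {
  if (is.null(daily) || nrow(daily) == 0) stop("empty daily climate series")
  stopifnot(all(c("date", "value") %in% names(daily)))
  stopifnot(all(months %in% 1:12))
  dates <- as.Date(daily$date)
  if (anyNA(dates)) stop("unparseable dates in daily climate series")
  keep <- (as.POSIXlt(dates)$mon + 1L) %in% months & !is.na(daily$value)
  if (anyDuplicated(dates[keep])) stop("duplicated dates in daily climate series")
  yr <- as.POSIXlt(dates)$year + 1900L
  df <- tibble::tibble(year = yr[keep], value = daily$value[keep])
  out <- dplyr::summarise(df, value = mean(.data$value),
                          n_days = dplyr::n(), .by = "year")
  out$n_expected <- vapply(out$year, window_days, integer(1), months = months)
  out <- out[out$n_days >= (1 - max_missing) * out$n_expected, , drop = FALSE]
  dplyr::arrange(out, .data$year)
}

window_days <- function(year, months) {
  dpm <- c(31L, 28L + as.integer(is_leap(year)), 31L, 30L, 31L, 30L,
           31L, 31L, 30L, 31L, 30L, 31L)
  sum(dpm[months])
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Build a climate panel from daily series of several populations
#'
#' @param daily Data frame with columns `population_id`, `date`, `value`.
#' @param variable_name Name recorded on the panel (e.g.
#'   `"mean_temperature"`).
#' @inheritParams seasonal_mean
#' @return A [climate_panel()].
#' @export
climate_panel_from_daily <- function(daily, variable_name, months = 2:5,
                                     max_missing = 0.1) {
  stopifnot(all(c("population_id", "date", "value") %in% names(daily)))
  parts <- lapply(split(daily, as.character(daily$population_id)), function(d) {
    out <- seasonal_mean(d, months = months, max_missing = max_missing)
    out$population_id <- d$population_id[1]
    out
  })
  long <- dplyr::bind_rows(parts)
  if (nrow(long) == 0) stop("no complete climate years in any population")
  p <- panel_from_long(long[, c("population_id", "year", "value")],
                       name = variable_name)
  climate_panel(variable_name, p$populations, p$years, p$values, p$mask)
}

#' Detrend and normalize a trait panel
#'
#' Removes each population's linear time trend (ordinary least-squares
#' regression of annual average value on calendar year, over that
#' population's observed years) and scales the residuals to unit sample
#' standard deviation. Synchrony is then measured in year-to-year
#' fluctuations relative to each population's own trend, not in shared
#' long-term trends or absolute level differences.
#'
#' @param panel A [trait_panel()]; every population needs at least 3
#'   observed years and non-zero residual variance.
#' @return A panel of the same shape; per population the output has mean 0
#'   and sample SD 1 on its observed years, mask unchanged.
#' @export
detrend_normalize <- function(panel) {
  vals <- panel$values
  for (i in seq_along(panel$populations)) {
    obs <- which(panel$mask[i, ])
    if (length(obs) < 3) {
      stop("population ", panel$populations[i], " has fewer than 3 observed years")
    }
    y <- panel$values[i, obs]
    x <- panel$years[obs]
    r <- stats::lm.fit(cbind(1, x), y)$residuals
    s <- stats::sd(r)
    if (!is.finite(s) || s < 1e-12 * max(1, stats::sd(y))) {
      stop("population ", panel$populations[i],
           " is exactly linear in year: zero residual variance")
    }
    vals[i, obs] <- r / s
  }
  new_panel(panel$name, panel$populations, panel$years, vals, panel$mask,
            class = class(panel))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean;
#' summarizes relative temporal variability of annual average trait
#' values.
#'
#' @param x Numeric vector, `length >= 2`, non-zero mean; `NA`s dropped.
#' @return `sd(x) / mean(x)`.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("CV needs at least 2 values")
  m <- mean(x)
  if (abs(m) < 1e-12 * max(abs(x), 1)) stop("CV undefined for zero mean")
  stats::sd(x) / m
}
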