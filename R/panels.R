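#' Population-by-year panels
#'
#' A panel holds annual average values for a set of populations over a set
#' of calendar years, together with an availability mask: monitoring
#' schemes start and stop in different years, so the set of populations
#' observed in any given year varies. `trait_panel()` wraps annual average
#' trait values (median laying date, mean clutch size, ...);
#' `climate_panel()` wraps seasonal-window climate means and shares the
#' same shape contract.
#'
#' @param name Trait name (one of `r paste(TRAIT_NAMES, collapse = ", ")`)
#'   or, for climate panels, the climate variable name.
#' @param populations Character vector of population identifiers (unique,
#'   in the row order of `values`).
#' @param years Integer vector of calendar years (column order of `values`).
#' @param values Numeric matrix, `length(populations)` x `length(years)`.
#'   Entries where `mask` is `FALSE` are ignored (stored as `NA`).
#' @param mask Logical matrix of the same shape: `TRUE` where a value was
#'   observed. Defaults to `!is.na(values)`.
#'
#' @return An object of class `trait_panel` (or `climate_panel`, which
#'   inherits the shape contract), a list with elements `name`,
#'   `populations`, `years`, `values`, `mask`.
#' @export
trait_panel <- function(name, populations, years, values, mask = NULL) {
  new_panel(name, populations, years, values, mask, class = "trait_panel")
}

#' @rdname trait_panel
#' @export
climate_panel <- function(name, populations, years, values, mask = NULL) {
  new_panel(name, populations, years, values, mask,
            class = c("climate_panel", "trait_panel"))
}

TRAIT_NAMES <- c("laying_date", "clutch_size", "fledgling_number",
                 "fledgling_success")

new_panel <- function(name, populations, years, values, mask, class) {
  populations <- as.character(populations)
  years <- as.integer(years)
  values <- as.matrix(values)
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  stopifnot(is.numeric(values), is.logical(mask))
  if (anyDuplicated(populations)) {
    stop("duplicated population_id in panel: ",
         paste(unique(populations[duplicated(populations)]), collapse = ", "))
  }
  if (!identical(dim(values), c(length(populations), length(years)))) {
    stop("panel `values` must be length(populations) x length(years)")
  }
  if (!identical(dim(mask), dim(values))) {
    stop("panel `mask` must have the same shape as `values`")
  }
  if (anyNA(values[mask])) {
    stop("panel has NA values where mask is TRUE")
  }
  values[!mask] <- NA_real_
  dimnames(values) <- dimnames(mask) <- list(populations, years)
  structure(
    list(name = as.character(name), populations = populations,
         years = years, values = values, mask = mask),
    class = class
  )
}

#' @export
print.trait_panel <- function(x, ...) {
  cat(sprintf(
    "<%s> %s: %d populations x %d years (%d-%d), %d observed cells (%.0f%%)\n",
    class(x)[1], x$name, length(x$populations), length(x$years),
    min(x$years), max(x$years), sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.trait_panel <- function(x) dim(x$values)

#' Number of observed years per population
#' @param panel A [trait_panel()].
#' @return Named integer vector.
#' @export
panel_years_per_population <- function(panel) {
  stats::setNames(rowSums(panel$mask), panel$populations)
}

#' Restrict a panel to a subset of populations (and optionally years)
#'
#' @param panel A [trait_panel()].
#' @param populations Character vector of population ids to keep (order
#'   preserved as given).
#' @param years Optional integer vector of years to keep.
#' @return A panel of the same class.
#' @export
panel_subset <- function(panel, populations = panel$populations,
                         years = panel$years) {
  missing_pop <- setdiff(populations, panel$populations)
  if (length(missing_pop)) {
    stop("unknown populations: ", paste(missing_pop, collapse = ", "))
  }
  i <- match(populations, panel$populations)
  j <- match(intersect(years, panel$years), panel$years)
  new_panel(panel$name, panel$populations[i], panel$years[j],
            panel$values[i, j, drop = FALSE], panel$mask[i, j, drop = FALSE],
            class = class(panel))
}

#' Drop populations with short observed series
#'
#' Long-term monitoring studies of hole-nesting passerines typically
#' require a minimum series length before a population enters a synchrony
#' analysis; the default of 9 observed years matches common practice for
#' these datasets.
#'
#' @param panel A [trait_panel()].
#' @param min_years Minimum number of observed years (default 9).
#' @return The panel restricted to populations with at least `min_years`
#'   observed years.
#' @export
drop_short_series <- function(panel, min_years = 9) {
  keep <- rowSums(panel$mask) >= min_years
  if (!any(keep)) {
    stop("no population has >= ", min_years, " observed years")
  }
  panel_subset(panel, panel$populations[keep])
}

#' Convert a panel to / from long format
#'
#' Long format has one row per observed population-year with columns
#' `population_id`, `year`, `value`: the on-disk interchange format.
#'
#' @param panel A [trait_panel()].
#' @return `panel_to_long()`: a tibble with one row per observed cell.
#' @export
panel_to_long <- function(panel) {
  idx <- which(panel$mask, arr.ind = TRUE)
  out <- tibble::tibble(
    population_id = panel$populations[idx[, 1]],
    year = panel$years[idx[, 2]],
    value = panel$values[idx]
  )
  dplyr::arrange(out, .data$population_id, .data$year)
}

#' @rdname panel_to_long
#' @param df Long-format data frame with columns `population_id`, `year`,
#'   `value`.
#' @param name Panel name.
#' @param populations Optional population ordering (default: sorted unique
#'   ids present in `df`).
#' @return `panel_from_long()`: a [trait_panel()].
#' @export
panel_from_long <- function(df, name, populations = NULL) {
  stopifnot(all(c("population_id", "year", "value") %in% names(df)))
  if (is.null(populations)) populations <- sort(unique(df$population_id))
  years <- sort(unique(as.integer(df$year)))
  values <- matrix(NA_real_, length(populations), length(years))
  i <- match(df$population_id, populations)
  j <- match(as.integer(df$year), years)
  if (anyNA(i)) stop("population_id in data not covered by `populations`")
  values[cbind(i, j)] <- df$value
  trait_panel(name, populations, years, values)
}
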