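#' Great-circle distance in kilometers
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param a,b Numeric length-2 vectors `(latitude, longitude)` in decimal
#'   degrees, or two-column matrices of such points.
#' @return Distance(s) in kilometers.
#' @export
haversine_km <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  check_coords(a); check_coords(b)
  # geosphere expects (lon, lat)
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = 6371000) / 1000
}

check_coords <- function(x) {
  if (any(!is.finite(x))) stop("non-finite coordinates")
  if (any(x[, 1] < -90 | x[, 1] > 90)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(x[, 2] < -180 | x[, 2] > 180)) {
    stop("longitude out of range [-180, 180]")
  }
  invisible(x)
}

#' Pairwise distance matrix between study sites
#'
#' @param sites Data frame with columns `population_id` and either
#'   `latitude`/`longitude` (great-circle distances) or `x_km`/`y_km`
#'   (planar Euclidean distances, used for simulated layouts).
#' @return A symmetric matrix of distances in kilometers with zero
#'   diagonal, with `dimnames` set to the population ids.
#' @export
distance_matrix <- function(sites) {
  stopifnot("population_id" %in% names(sites))
  ids <- as.character(sites$population_id)
  if (anyDuplicated(ids)) stop("duplicated population_id in sites")
  if (all(c("latitude", "longitude") %in% names(sites))) {
    pts <- cbind(sites$latitude, sites$longitude)
    check_coords(pts)
    n <- nrow(pts)
    d <- matrix(0, n, n)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        j <- (i + 1):n
        d[i, j] <- d[j, i] <- haversine_km(
          matrix(pts[i, ], length(j), 2, byrow = TRUE),
          pts[j, , drop = FALSE])
      }
    }
  } else if (all(c("x_km", "y_km") %in% names(sites))) {
    d <- as.matrix(stats::dist(cbind(sites$x_km, sites$y_km)))
  } else {
    stop("sites need latitude/longitude or x_km/y_km columns")
  }
  dimnames(d) <- list(ids, ids)
  d
}
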