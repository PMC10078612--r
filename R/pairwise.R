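#' Empirical pairwise correlations by distance
#'
#' For every unordered pair of populations with enough overlapping
#' observed years, the Pearson correlation of their series over the
#' overlap, together with the pair distance and the overlap length. These
#' are the model-free points plotted under the fitted correlogram; pairs
#' with a constant series over the overlap are skipped with a warning.
#'
#' @param panel A detrended, normalized [trait_panel()].
#' @param D Distance matrix in km aligned with the panel.
#' @param min_overlap Minimum number of overlapping years (default 5,
#'   must be at least 3).
#' @return Tibble with columns `pop_a`, `pop_b`, `distance_km`,
#'   `pearson_r`, `n_overlap`.
#' @export
pairwise_empirical_correlations <- function(panel, D, min_overlap = 5) {
  if (min_overlap < 3) stop("min_overlap must be >= 3")
  D <- as.matrix(D)
  k <- length(panel$populations)
  stopifnot(nrow(D) == k)
  rows <- list()
  for (i in seq_len(max(k - 1, 0))) {
    for (j in (i + 1):k) {
      ov <- which(panel$mask[i, ] & panel$mask[j, ])
      if (length(ov) < min_overlap) next
      a <- panel$values[i, ov]; b <- panel$values[j, ov]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("constant series over overlap for pair ",
                panel$populations[i], "-", panel$populations[j],
                "; pair skipped", call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pop_a = panel$populations[i], pop_b = panel$populations[j],
        distance_km = D[i, j], pearson_r = stats::cor(a, b),
        n_overlap = length(ov))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(pop_a = character(), pop_b = character(),
                          distance_km = numeric(), pearson_r = numeric(),
                          n_overlap = integer()))
  }
  dplyr::bind_rows(rows)
}
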