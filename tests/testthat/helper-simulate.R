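# Shared fixture builders. Everything is generated in code; no files.

# A complete panel simulated from the synchrony model at `truth`, with the
# site layout drawn uniformly in an L x L km plane. Returns panel + D.
sim_truth_panel <- function(seed, n_sites, n_years, truth, L = 2000) {
  layout <- generate_sites(n_sites, c(L, L), seed = seed)
  mask <- matrix(TRUE, n_sites, n_years)
  panel <- withr::with_seed(seed + 1L,
    simulate_mvn_panel(truth, mask, layout$D,
                       years = 2000L + seq_len(n_years),
                       populations = layout$sites$population_id))
  list(panel = panel, D = layout$D)
}

# Small hand-built panel: values matrix (pops x years), complete mask.
tiny_panel <- function(values, years = NULL) {
  values <- as.matrix(values)
  if (is.null(years)) years <- 2000L + seq_len(ncol(values))
  trait_panel("toy", paste0("p", seq_len(nrow(values))), years, values)
}

# Distance matrix from explicit pairwise distances (2 or 3 sites).
tiny_D <- function(d12, d13 = NULL, d23 = NULL) {
  if (is.null(d13)) {
    m <- matrix(c(0, d12, d12, 0), 2, 2)
    dimnames(m) <- list(c("p1", "p2"), c("p1", "p2"))
  } else {
    m <- matrix(c(0, d12, d13, d12, 0, d23, d13, d23, 0), 3, 3)
    dimnames(m) <- list(paste0("p", 1:3), paste0("p", 1:3))
  }
  m
}

# Independent dense-matrix MVN log-density: the oracle for total_loglik.
# Uses determinant() + solve(), no Cholesky factorization shared with the
# implementation path.
dense_mvn_loglik <- function(y, sigma) {
  k <- length(y)
  -0.5 * (k * log(2 * pi) +
            as.numeric(determinant(sigma, logarithm = TRUE)$modulus) +
            drop(t(y) %*% solve(sigma) %*% y))
}

# Brood record row constructor with sensible defaults.
brood <- function(population_id = "A", year = 2000L, laying_date = 10,
                  clutch_size = 8, fledgling_number = 6,
                  is_first_clutch = TRUE, is_experimental = FALSE) {
  tibble::tibble(population_id = population_id, year = as.integer(year),
                 laying_date = laying_date, clutch_size = clutch_size,
                 fledgling_number = fledgling_number,
                 is_first_clutch = is_first_clutch,
                 is_experimental = is_experimental)
}
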