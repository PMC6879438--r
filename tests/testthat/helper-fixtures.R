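# Fixtures built in code at test time.

# 3x3x3 volume: hot centre (10), six face neighbours at 5, the rest at 1.
cross_volume <- function() {
  g <- array(1, c(3, 3, 3))
  g[2, 2, 2] <- 10
  g[1, 2, 2] <- g[3, 2, 2] <- g[2, 1, 2] <- g[2, 3, 2] <-
    g[2, 2, 1] <- g[2, 2, 3] <- 5
  pet_volume(g, c(5.5, 5.5, 3.3), "cross")
}

# Uniform rectangular lesion embedded in a low background.
block_volume <- function(value = 6, dim = c(8, 8, 6),
                         block = list(3:6, 3:6, 2:5), bg = 0.2) {
  g <- array(bg, dim)
  g[block[[1]], block[[2]], block[[3]]] <- value
  pet_volume(g, c(5.5, 5.5, 3.3), "block")
}

# Random masked quantized volume for GLCM oracle sweeps.
random_quantized <- function(dims, G, mask_frac = 0.7) {
  lv <- array(NA_integer_, dims)
  m <- array(runif(prod(dims)) < mask_frac, dims)
  if (!any(m)) m[1, 1, 1] <- TRUE
  lv[m] <- sample.int(G, sum(m), replace = TRUE)
  structure(list(levels = lv, n_bins = as.integer(G), range = c(0, 1),
                 binning = "fixture"), class = "quantized_volume")
}

# Random normalized symmetric GLCM probability matrix.
random_sym_p <- function(G) {
  M <- matrix(rexp(G * G), G, G)
  M <- M + t(M)
  M / sum(M)
}

# Small fast cohort configuration for imaging tests (two scanners so that
# every batch stays above the ComBat minimum at small n).
tiny_cohort_config <- function(n = 5, seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_patients = n, grid_dim = c(28, 28, 18),
                   lesions_per_patient = c(1, 2),
                   lesion_radius_mm = c(10, 16),
                   scanner_labels = c("A", "B"),
                   scanner_probs = c(0.55, 0.45),
                   batch_shift = c(0, 0.2), batch_scale = c(1, 1.1),
                   seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# Fast single-lesion configuration used for the end-to-end simulations.
power_cohort_config <- function(n, hazard_log_hr, seed) {
  cohort_config(n_patients = n, grid_dim = c(28, 28, 18),
                lesions_per_patient = c(1, 1), lesion_radius_mm = c(10, 16),
                hazard_log_hr = hazard_log_hr, outcome_logit_coeffs = NULL,
                censor_rate = 0.2, seed = seed)
}
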