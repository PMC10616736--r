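# Small deterministic fixtures, built in code at test time.

# 3 sites x 2 years x 3 occasions with injected missingness
tiny_history <- function() {
  y <- array(NA_integer_, c(3, 2, 3))
  y[1, 1, ] <- c(0L, 1L, 0L)
  y[1, 2, ] <- c(0L, 0L, 0L)
  y[2, 1, ] <- c(2L, NA, 1L)
  y[2, 2, ] <- c(0L, 2L, 2L)
  y[3, 1, ] <- c(NA, NA, NA)
  y[3, 2, ] <- c(0L, NA, 0L)
  detection_history(y, site_ids = c("s1", "s2", "s3"),
                    year_labels = c("2018", "2019"))
}

tiny_covariates <- function(standardized = TRUE) {
  cov <- site_covariates(c("s1", "s2", "s3"),
                         habitat5km = c(0.2, 0.5, 0.9),
                         habitat1km = c(0.1, 0.6, 0.8),
                         ecoregion = c("GreatBasin", "GreatBasin",
                                       "SierraNevada"))
  if (standardized) standardize_covariates(cov) else cov
}

tiny_params <- function(n_sites = 3) {
  ms_params(occ_intercept = 0.2, occ_beta_habitat = 1.1,
            occ_beta_ecoregion = 1.5,
            rep_intercept = -0.4, rep_beta_habitat = 0.8,
            rep_beta_ecoregion = 0.9,
            det_intercepts = c(-0.5, -0.8, -1.1),
            det_beta_habitat = c(0.6, 0.1, -0.2),
            occ_precision = 1.3, rep_precision = 0.7,
            occ_random_effects = seq(-0.3, 0.3, length.out = n_sites),
            rep_random_effects = seq(0.2, -0.2, length.out = n_sites))
}

# small simulated dataset for sampler tests
small_sim <- function(seed = 42, n_sites = 15, n_sierra = 3, n_years = 2,
                      n_occasions = 5) {
  set.seed(seed)
  simulate_dataset(default_truth(),
                   simulation_design(n_sites = n_sites, n_sierra = n_sierra,
                                     n_years = n_years,
                                     n_occasions = n_occasions,
                                     first_year_start = 1))
}
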