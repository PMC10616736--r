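test_that("inv_logit is symmetric and numerically stable", {
  expect_equal(inv_logit(0), 0.5)
  for (x in c(-5, -0.3, 0.7, 12, 300))
    expect_equal(inv_logit(x), 1 - inv_logit(-x), tolerance = 1e-12)
  expect_equal(inv_logit(37), 1.0)
  expect_true(is.finite(inv_logit(700)) && is.finite(inv_logit(-700)))
  expect_gt(inv_logit(-700), 0 - 1e-300)
})

test_that("occupancy and reproduction follow the logit-linear submodels", {
  cov <- tiny_covariates()
  p0 <- ms_params(n_sites = 3)
  expect_equal(unname(occupancy_and_reproduction(cov, p0, 1)), c(0.5, 0.5))

  # reference coding: a GreatBasin site gets no ecoregion contribution
  p <- tiny_params()
  pr <- occupancy_and_reproduction(cov, p, 1)
  lp <- p$occ_intercept + p$occ_random_effects[1] +
    p$occ_beta_habitat * cov$habitat5km_std[1]
  expect_equal(unname(pr["psi"]), inv_logit(lp))

  # switching to SierraNevada raises logit(psi) by exactly the contrast
  p58 <- tiny_params(); p58$occ_beta_ecoregion <- 5.8
  cov2 <- cov; cov2$ecoregion[1] <- "SierraNevada"
  d <- qlogis(occupancy_and_reproduction(cov2, p58, 1)[["psi"]]) -
    qlogis(occupancy_and_reproduction(cov, p58, 1)[["psi"]])
  expect_equal(d, 5.8, tolerance = 1e-9)

  expect_error(occupancy_and_reproduction(tiny_covariates(FALSE), p, 1),
               "standardized")
  expect_error(occupancy_and_reproduction(cov, p, 9), "invalid site")
})

test_that("detection submodels share the logit-linear form in fine habitat", {
  cov <- tiny_covariates()
  expect_equal(unname(detection_probs(cov, ms_params(n_sites = 3), 2)),
               c(0.5, 0.5, 0.5))
  p <- tiny_params()
  # zero (or near-zero) slopes leave p23/p33 flat across the gradient
  pflat <- tiny_params(); pflat$det_beta_habitat <- c(0.8, 0, 0)
  d1 <- detection_probs(cov, pflat, 1); d3 <- detection_probs(cov, pflat, 3)
  expect_equal(d1[["p23"]], d3[["p23"]])
  expect_equal(d1[["p33"]], d3[["p33"]])
  expect_gt(d3[["p22"]], d1[["p22"]])  # positive slope: monotone increasing
})

test_that("the observation matrix encodes no false positives", {
  th <- observation_matrix(0.5, 0.4, 0.3)
  expect_equal(unname(th),
               rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.3, 0.4, 0.3)))
  expect_error(observation_matrix(0.5, 0.7, 0.4),
               class = "msoccu_constraint_violation")
  set.seed(2)
  for (r in 1:20) {
    p <- runif(3, 0.05, 0.45)
    th <- observation_matrix(p[1], p[2], p[3])
    expect_equal(unname(rowSums(th)), c(1, 1, 1), tolerance = 1e-12)
    expect_identical(unname(th[1, ]), c(1, 0, 0))
    expect_identical(th["adults_only", "y2"], 0)
  }
})

test_that("state priors form a proper probability vector", {
  set.seed(3)
  for (r in 1:20) {
    phi <- state_prob_vector(runif(1), runif(1))
    expect_equal(sum(phi), 1, tolerance = 1e-12)
    expect_true(all(phi >= 0 & phi <= 1))
  }
})

test_that("site-year marginal likelihood matches enumeration", {
  theta <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.3, 0.4, 0.3))
  phi <- rep(1 / 3, 3)
  expect_equal(site_year_marginal_loglik(c(0, 0), phi, theta),
               log((1 + 0.25 + 0.09) / 3), tolerance = 1e-12)
  expect_equal(site_year_marginal_loglik(2, c(0.5, 0.3, 0.2), theta),
               log(0.2 * 0.3), tolerance = 1e-12)
  expect_identical(site_year_marginal_loglik(c(NA, NA), phi, theta), 0)

  set.seed(4)
  for (r in 1:25) {
    p <- runif(3, 0.05, 0.45)
    th <- observation_matrix(p[1], p[2], p[3])
    ph <- state_prob_vector(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95))
    y <- sample(c(0L, 1L, 2L, NA), sample(1:8, 1), replace = TRUE)
    expect_equal(site_year_marginal_loglik(y, ph, th),
                 oracle_site_year_loglik(y, ph, th), tolerance = 1e-12)
  }
})

test_that("observed cubs force the with-cubs state; adults exclude vacancy", {
  p <- runif(3, 0.1, 0.4)
  th <- observation_matrix(p[1], p[2], p[3])
  ph <- state_prob_vector(0.6, 0.4)
  # y containing 2: only z = with-cubs contributes
  expect_equal(site_year_marginal_loglik(c(2, 0), ph, th),
               log(ph[3] * th[3, 3] * th[3, 1]), tolerance = 1e-12)
  # y containing 1: vacancy contributes nothing
  ll <- site_year_marginal_loglik(c(1, 0), ph, th)
  expect_equal(ll, log(ph[2] * th[2, 2] * th[2, 1] +
                         ph[3] * th[3, 2] * th[3, 1]), tolerance = 1e-12)
})

test_that("likelihood is invariant to occasion order within a site-year", {
  set.seed(5)
  p <- runif(3, 0.1, 0.4)
  th <- observation_matrix(p[1], p[2], p[3])
  ph <- state_prob_vector(0.5, 0.3)
  y <- c(0L, 2L, NA, 1L, 0L, 2L)
  base <- site_year_marginal_loglik(y, ph, th)
  for (r in 1:10)
    expect_equal(site_year_marginal_loglik(sample(y), ph, th), base,
                 tolerance = 1e-12)
})

test_that("total likelihood is additive and matches the double-loop oracle", {
  dh <- tiny_history(); cov <- tiny_covariates(); p <- tiny_params()
  expect_equal(total_loglik(dh, cov, p), oracle_total_loglik(dh, cov, p),
               tolerance = 1e-10)

  # a 5-site, 2-year, 3-occasion fixture
  set.seed(6)
  sim <- small_sim(seed = 6, n_sites = 5, n_sierra = 1, n_years = 2,
                   n_occasions = 3)
  pp <- sim$truth$params
  expect_equal(total_loglik(sim$history, sim$covariates, pp),
               oracle_total_loglik(sim$history, sim$covariates, pp),
               tolerance = 1e-10)

  # duplicating every site-year doubles the total
  y2 <- array(NA_integer_, c(dh$n_sites, 2 * dh$n_years, dh$n_occasions))
  y2[, 1:2, ] <- dh$y; y2[, 3:4, ] <- dh$y
  dh2 <- detection_history(y2, site_ids = dh$site_ids)
  expect_equal(total_loglik(dh2, cov, p), 2 * total_loglik(dh, cov, p),
               tolerance = 1e-10)

  # the total decomposes into its per-site-year terms
  expect_equal(total_loglik(dh, cov, p),
               sum(vapply(seq_len(dh$n_sites), function(i) {
                 pr <- occupancy_and_reproduction(cov, p, i)
                 d <- detection_probs(cov, p, i)
                 th <- observation_matrix(d[1], d[2], d[3])
                 ph <- state_prob_vector(pr[["psi"]], pr[["R"]])
                 sum(vapply(seq_len(dh$n_years), function(j)
                   site_year_marginal_loglik(dh$y[i, j, ], ph, th),
                   numeric(1)))
               }, numeric(1))), tolerance = 1e-12)
})

test_that("p33 = 0 makes any observed cub impossible", {
  theta0 <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(0.6, 0.4, 0))
  expect_identical(site_year_marginal_loglik(c(0, 2), c(0.2, 0.3, 0.5),
                                             theta0), -Inf)
  dh <- tiny_history(); cov <- tiny_covariates()
  p <- tiny_params()
  p$det_intercepts[3] <- -800  # p33 underflows to exactly 0
  p$det_beta_habitat[3] <- 0
  expect_identical(total_loglik(dh, cov, p), -Inf)
})

test_that("violating the multinomial detection constraint yields -Inf", {
  dh <- tiny_history(); cov <- tiny_covariates()
  p <- tiny_params()
  p$det_intercepts[2:3] <- c(2, 2)  # p23 + p33 > 1 everywhere
  expect_identical(total_loglik(dh, cov, p), -Inf)
})

test_that("with R = 0 the model collapses to two-state occupancy", {
  set.seed(7)
  truth <- default_truth()
  truth$rep_intercept <- -800; truth$rep_beta_habitat <- 0
  truth$rep_beta_ecoregion <- 0; truth$rep_precision <- 1e12
  sim <- simulate_dataset(truth, simulation_design(
    n_sites = 12, n_sierra = 2, n_years = 2, n_occasions = 4,
    first_year_start = 1))
  expect_true(all(sim$history$y %in% c(0L, 1L) | is.na(sim$history$y)))
  p <- sim$truth$params
  expect_equal(total_loglik(sim$history, sim$covariates, p),
               oracle_twostate_loglik(sim$history, sim$covariates, p),
               tolerance = 1e-10)
})

test_that("the prior is proper over its support", {
  p <- tiny_params()
  pr <- prior_spec()
  base <- log_prior(p, pr)
  expect_true(is.finite(base))
  # zero fixed effects maximize the fixed-effect prior term
  p0 <- tiny_params()
  p0$occ_intercept <- 0; p0$occ_beta_habitat <- 0
  p0$occ_beta_ecoregion <- 0; p0$rep_intercept <- 0
  p0$rep_beta_habitat <- 0; p0$rep_beta_ecoregion <- 0
  p0$det_intercepts <- c(0, 0, 0); p0$det_beta_habitat <- c(0, 0, 0)
  expect_gt(log_prior(p0, pr), base)
  # doubling a random effect strictly decreases the prior
  p2 <- tiny_params()
  p2$occ_random_effects[1] <- 2 * p2$occ_random_effects[1]
  expect_lt(log_prior(p2, pr), base)
  # random-effect sd above its uniform upper bound has zero support
  p3 <- tiny_params()
  p3$occ_precision <- 1 / (10.0001)^2
  expect_identical(log_prior(p3, pr), -Inf)
})
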