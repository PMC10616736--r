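test_that("retained draw counts follow the burn-in/thinning arithmetic", {
  expect_identical(retained_per_chain(mcmc_config()), 2500L)
  cfg <- mcmc_config(n_iterations = 1000, burn_in = 500, thin = 10,
                     n_chains = 3)
  expect_identical(retained_per_chain(cfg), 50L)
  expect_identical(cfg$n_chains * retained_per_chain(cfg), 150L)
  expect_error(mcmc_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(fix = list(nonsense = 1)), "nonsense")
})

test_that("chains initialize at the maximum observed state, reproducibly", {
  sim <- small_sim(21)
  cfg <- mcmc_config(n_chains = 2, seed = 9,
                     n_iterations = 100, burn_in = 50, thin = 1)
  ini <- initialize_chains(sim$history, sim$covariates, cfg)
  prep <- msoccu:::sy_counts(sim$history)
  for (r in seq_len(nrow(prep$counts))) {
    if (prep$counts[r, 3] > 0) expect_identical(ini[[1]]$z[r], 2L)
    else if (prep$counts[r, 2] > 0) expect_identical(ini[[1]]$z[r], 1L)
  }
  # distinct overdispersed starts per chain, identical under the same seed
  expect_false(identical(ini[[1]]$params, ini[[2]]$params))
  ini2 <- initialize_chains(sim$history, sim$covariates, cfg)
  expect_identical(ini, ini2)
})

test_that("all-missing site-years initialize from the state prior", {
  y <- array(NA_integer_, c(4, 1, 3))
  y[1, 1, ] <- c(0L, 0L, 0L)
  dh <- detection_history(y)
  cov <- standardize_covariates(site_covariates(
    dh$site_ids, c(0.1, 0.4, 0.6, 0.9), c(0.2, 0.3, 0.7, 0.8),
    c("GreatBasin", "GreatBasin", "SierraNevada", "SierraNevada")))
  cfg <- mcmc_config(n_chains = 1, seed = 3, n_iterations = 10,
                     burn_in = 5, thin = 1)
  ini <- initialize_chains(dh, cov, cfg)
  expect_true(all(ini[[1]]$z %in% 0:2))
})

test_that("latent-state sampling matches the enumerated conditional", {
  cov <- tiny_covariates()
  p <- tiny_params()
  dh <- tiny_history()
  set.seed(31)
  # forced state: any observed cub pins z = with-cubs (site 2 both years)
  z <- sample_latent_states(dh, cov, p)
  expect_identical(z["s2", "2018"], 2L)
  expect_identical(z["s2", "2019"], 2L)

  # empirical conditional over repeated draws vs enumeration, site 1 year 1
  pr <- occupancy_and_reproduction(cov, p, 1)
  d <- detection_probs(cov, p, 1)
  theta <- observation_matrix(d[1], d[2], d[3])
  phi <- state_prob_vector(pr[["psi"]], pr[["R"]])
  expected <- oracle_latent_conditional(dh$y[1, 1, ], phi, theta)
  n <- 4000
  draws <- replicate(n, sample_latent_states(dh, cov, p)["s1", "2018"])
  emp <- tabulate(draws + 1L, 3) / n
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
  expect_true(all(abs(emp - expected) <= 3 * se + 1e-9))

  # all-missing history draws from the prior phi (site 3, year 1)
  pr3 <- occupancy_and_reproduction(cov, p, 3)
  phi3 <- state_prob_vector(pr3[["psi"]], pr3[["R"]])
  draws3 <- replicate(n, sample_latent_states(dh, cov, p)["s3", "2018"])
  emp3 <- tabulate(draws3 + 1L, 3) / n
  se3 <- sqrt(phi3 * (1 - phi3) / n)
  expect_true(all(abs(emp3 - phi3) <= 3.5 * se3 + 1e-9))
})

test_that("a parameter sweep with fixed latent states moves the chain", {
  sim <- small_sim(22)
  p <- sim$truth$params
  set.seed(5)
  z <- sample_latent_states(sim$history, sim$covariates, p)
  cfg <- mcmc_config(n_iterations = 10, burn_in = 5, proposal_scale = 0.3)
  set.seed(6)
  p2 <- update_parameters(sim$history, sim$covariates, p, z, cfg)
  expect_s3_class(p2, "ms_params")
  expect_false(identical(p2$occ_intercept, p$occ_intercept) &&
                 identical(p2$det_intercepts, p$det_intercepts))
  # fixed entries are honoured
  cfg2 <- mcmc_config(n_iterations = 10, burn_in = 5,
                      fix = list(occ_intercept = p$occ_intercept))
  set.seed(7)
  p3 <- update_parameters(sim$history, sim$covariates, p, z, cfg2)
  expect_identical(p3$occ_intercept, p$occ_intercept)
})

test_that("the sampler never leaves the multinomial detection support", {
  sim <- small_sim(23)
  cfg <- mcmc_config(n_chains = 1, n_iterations = 1500, burn_in = 500,
                     thin = 1, seed = 2, proposal_scale = 1.5, adapt = FALSE)
  fit <- run_mcmc(sim$history, sim$covariates, cfg)
  m <- as.matrix(fit)
  x1 <- sim$covariates$habitat1km_std
  for (r in seq_len(nrow(m))) {
    p23 <- inv_logit(m[r, "det_intercept_p23"] + m[r, "det_beta_p23"] * x1)
    p33 <- inv_logit(m[r, "det_intercept_p33"] + m[r, "det_beta_p33"] * x1)
    expect_true(all(p23 + p33 <= 1))
  }
})

test_that("burn-in adaptation lands acceptance rates in a workable band", {
  sim <- small_sim(24)
  cfg <- mcmc_config(n_chains = 1, n_iterations = 6000, burn_in = 3000,
                     thin = 5, seed = 4)
  fit <- run_mcmc(sim$history, sim$covariates, cfg)
  fixed_acc <- fit$accept[1, msoccu:::fixed_param_names()]
  expect_true(all(fixed_acc > 0.1 & fixed_acc < 0.6))
})

test_that("with no observations the posterior reproduces the prior", {
  y <- array(NA_integer_, c(8, 1, 4))
  dh <- detection_history(y)
  set.seed(12)
  cov <- standardize_covariates(site_covariates(
    dh$site_ids, runif(8), runif(8),
    rep(c("GreatBasin", "SierraNevada"), 4)))
  cfg <- mcmc_config(n_chains = 1, n_iterations = 110000, burn_in = 10000,
                     thin = 20, seed = 8, save_latent = FALSE)
  fit <- run_mcmc(dh, cov, cfg)
  draws <- as.matrix(fit)[, "occ_beta_habitat"]
  expect_length(draws, 5000)
  ks <- suppressWarnings(ks.test(draws, "pnorm", 0, 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seeds give bit-identical fits", {
  sim <- small_sim(25)
  cfg <- mcmc_config(n_chains = 2, n_iterations = 400, burn_in = 200,
                     thin = 2, seed = 99)
  f1 <- run_mcmc(sim$history, sim$covariates, cfg)
  f2 <- run_mcmc(sim$history, sim$covariates, cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$latent_state_draws, f2$latent_state_draws)
})

test_that("impossible initial states are reported, not sampled through", {
  sim <- small_sim(26)
  cfg <- mcmc_config(n_iterations = 100, burn_in = 50,
                     fix = list(sd_occ = 25))  # outside Uniform(0, 10)
  expect_error(run_mcmc(sim$history, sim$covariates, cfg),
               "non-finite log posterior")
})

test_that("a constant ecoregion covariate is refused with an explanation", {
  y <- array(0L, c(4, 1, 3))
  dh <- detection_history(y)
  cov <- standardize_covariates(site_covariates(
    dh$site_ids, c(0.1, 0.3, 0.6, 0.9), c(0.2, 0.4, 0.5, 0.8),
    rep("GreatBasin", 4)))
  expect_error(run_mcmc(dh, cov, mcmc_config(n_iterations = 100,
                                             burn_in = 10)),
               "ecoregion is constant")
})

test_that("posterior summaries are invariant to chain relabelling", {
  sim <- small_sim(27)
  cfg <- mcmc_config(n_chains = 3, n_iterations = 600, burn_in = 300,
                     thin = 3, seed = 5)
  fit <- run_mcmc(sim$history, sim$covariates, cfg)
  s1 <- summarize_posterior(fit, c("occ_intercept", "rep_intercept"))
  fit2 <- fit
  fit2$draws <- fit$draws[c(3, 1, 2), , ]
  s2 <- summarize_posterior(fit2, c("occ_intercept", "rep_intercept"))
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$q2.5, s2$q2.5)
  expect_equal(s1$rhat, s2$rhat)
})

test_that("halving the thinning interval leaves summaries consistent", {
  sim <- small_sim(28)
  base <- list(n_chains = 2, n_iterations = 16000, burn_in = 4000, seed = 10)
  f40 <- run_mcmc(sim$history, sim$covariates,
                  do.call(mcmc_config, c(base, thin = 40)))
  f20 <- run_mcmc(sim$history, sim$covariates,
                  do.call(mcmc_config, c(base, thin = 20)))
  s40 <- summarize_posterior(f40, c("occ_intercept", "occ_beta_habitat"))
  s20 <- summarize_posterior(f20, c("occ_intercept", "occ_beta_habitat"))
  mcse <- s20$sd / sqrt(100)  # conservative effective-size guess
  expect_true(all(abs(s40$mean - s20$mean) < 6 * mcse))
})
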