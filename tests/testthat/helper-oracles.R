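# Independent oracles, coded from first principles and kept free of the
# package's likelihood code paths.

# marginal likelihood of one occasion vector by explicit enumeration over
# the three latent states and every occasion
oracle_site_year_loglik <- function(y, phi, theta) {
  y <- y[!is.na(y)]
  total <- 0
  for (z in 1:3) {
    term <- phi[z]
    for (t in seq_along(y)) term <- term * theta[z, y[t] + 1]
    total <- total + term
  }
  log(total)
}

# dataset log-likelihood by a naive double loop, recomputing every
# probability from the linear predictors directly
oracle_total_loglik <- function(data, cov, params) {
  eco <- as.numeric(cov$ecoregion == "SierraNevada")
  ll <- 0
  for (i in seq_len(data$n_sites)) {
    psi <- 1 / (1 + exp(-(params$occ_intercept +
                            params$occ_random_effects[i] +
                            params$occ_beta_habitat * cov$habitat5km_std[i] +
                            params$occ_beta_ecoregion * eco[i])))
    R <- 1 / (1 + exp(-(params$rep_intercept +
                          params$rep_random_effects[i] +
                          params$rep_beta_habitat * cov$habitat5km_std[i] +
                          params$rep_beta_ecoregion * eco[i])))
    p <- 1 / (1 + exp(-(params$det_intercepts +
                          params$det_beta_habitat * cov$habitat1km_std[i])))
    stopifnot(p[2] + p[3] <= 1)
    phi <- c(1 - psi, psi * (1 - R), psi * R)
    theta <- rbind(c(1, 0, 0),
                   c(1 - p[1], p[1], 0),
                   c(1 - p[2] - p[3], p[2], p[3]))
    for (j in seq_len(data$n_years))
      ll <- ll + oracle_site_year_loglik(data$y[i, j, ], phi, theta)
  }
  ll
}

# joint likelihood by brute-force enumeration over ALL latent-state
# assignments of the dataset (3^n_site_years terms); exercises the
# factorization the marginal likelihood relies on
oracle_enumerated_loglik <- function(data, cov, params) {
  eco <- as.numeric(cov$ecoregion == "SierraNevada")
  sy <- expand.grid(year = seq_len(data$n_years),
                    site = seq_len(data$n_sites))
  nsy <- nrow(sy)
  phis <- thetas <- vector("list", data$n_sites)
  for (i in seq_len(data$n_sites)) {
    psi <- plogis(params$occ_intercept + params$occ_random_effects[i] +
                    params$occ_beta_habitat * cov$habitat5km_std[i] +
                    params$occ_beta_ecoregion * eco[i])
    R <- plogis(params$rep_intercept + params$rep_random_effects[i] +
                  params$rep_beta_habitat * cov$habitat5km_std[i] +
                  params$rep_beta_ecoregion * eco[i])
    p <- plogis(params$det_intercepts +
                  params$det_beta_habitat * cov$habitat1km_std[i])
    phis[[i]] <- c(1 - psi, psi * (1 - R), psi * R)
    thetas[[i]] <- rbind(c(1, 0, 0),
                         c(1 - p[1], p[1], 0),
                         c(1 - p[2] - p[3], p[2], p[3]))
  }
  total <- 0
  for (code in 0:(3^nsy - 1)) {
    rest <- code
    term <- 1
    for (r in seq_len(nsy)) {
      z <- rest %% 3
      rest <- rest %/% 3
      i <- sy$site[r]; j <- sy$year[r]
      term <- term * phis[[i]][z + 1]
      yv <- data$y[i, j, ]
      yv <- yv[!is.na(yv)]
      for (t in seq_along(yv)) term <- term * thetas[[i]][z + 1, yv[t] + 1]
    }
    total <- total + term
  }
  log(total)
}

# directly coded two-state (occupied/unoccupied) occupancy likelihood:
# detection is Bernoulli(p22) per active occasion given occupancy
oracle_twostate_loglik <- function(data, cov, params) {
  eco <- as.numeric(cov$ecoregion == "SierraNevada")
  ll <- 0
  for (i in seq_len(data$n_sites)) {
    psi <- plogis(params$occ_intercept + params$occ_random_effects[i] +
                    params$occ_beta_habitat * cov$habitat5km_std[i] +
                    params$occ_beta_ecoregion * eco[i])
    p <- plogis(params$det_intercepts[1] +
                  params$det_beta_habitat[1] * cov$habitat1km_std[i])
    for (j in seq_len(data$n_years)) {
      yv <- data$y[i, j, ]
      yv <- yv[!is.na(yv)]
      stopifnot(all(yv %in% 0:1))
      nd <- sum(yv == 1)
      lik <- psi * p^nd * (1 - p)^(length(yv) - nd) +
        (1 - psi) * as.numeric(nd == 0)
      ll <- ll + log(lik)
    }
  }
  ll
}

# exact latent-state conditional by enumeration, for one site-year
oracle_latent_conditional <- function(y, phi, theta) {
  y <- y[!is.na(y)]
  w <- numeric(3)
  for (z in 1:3) {
    w[z] <- phi[z]
    for (t in seq_along(y)) w[z] <- w[z] * theta[z, y[t] + 1]
  }
  w / sum(w)
}
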