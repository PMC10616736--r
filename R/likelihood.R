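#' Parameters of the multistate occupancy model
#'
#' Collects every parameter of the three-level model: logit-linear occupancy
#' (psi) and conditional reproduction (R) submodels with a coarse-habitat
#' slope, an ecoregion contrast (SierraNevada vs the GreatBasin reference)
#' and site-level random intercepts; and three logit-linear detection
#' submodels with a fine-habitat slope each.  Detection probabilities are,
#' per occasion: `p22` adult detection given adults-only, `p23` adult-only
#' observation given adults-with-cubs, `p33` cub detection given
#' adults-with-cubs.
#'
#' @param occ_intercept,occ_beta_habitat,occ_beta_ecoregion fixed effects of
#'   the occupancy submodel (logit scale).
#' @param rep_intercept,rep_beta_habitat,rep_beta_ecoregion fixed effects of
#'   the reproduction submodel (logit scale).
#' @param det_intercepts,det_beta_habitat length-3 numeric vectors, ordered
#'   `(p22, p23, p33)` (logit scale).
#' @param occ_random_effects,rep_random_effects per-site random intercepts,
#'   shared across years within a site; default all zero.
#' @param occ_precision,rep_precision precisions (1/variance) of the
#'   random-effect distributions; must be strictly positive.
#' @param n_sites number of sites, used to size default random effects.
#' @return An object of class `ms_params`.
#' @export
ms_params <- function(occ_intercept = 0, occ_beta_habitat = 0,
                      occ_beta_ecoregion = 0,
                      rep_intercept = 0, rep_beta_habitat = 0,
                      rep_beta_ecoregion = 0,
                      det_intercepts = c(0, 0, 0),
                      det_beta_habitat = c(0, 0, 0),
                      occ_random_effects = NULL, rep_random_effects = NULL,
                      occ_precision = 1, rep_precision = 1,
                      n_sites = NULL) {
  if (is.null(occ_random_effects))
    occ_random_effects <- rep(0, if (is.null(n_sites)) 0L else n_sites)
  if (is.null(rep_random_effects))
    rep_random_effects <- rep(0, if (is.null(n_sites)) 0L else n_sites)
  p <- list(occ_intercept = occ_intercept,
            occ_beta_habitat = occ_beta_habitat,
            occ_beta_ecoregion = occ_beta_ecoregion,
            rep_intercept = rep_intercept,
            rep_beta_habitat = rep_beta_habitat,
            rep_beta_ecoregion = rep_beta_ecoregion,
            det_intercepts = as.numeric(det_intercepts),
            det_beta_habitat = as.numeric(det_beta_habitat),
            occ_random_effects = as.numeric(occ_random_effects),
            rep_random_effects = as.numeric(rep_random_effects),
            occ_precision = occ_precision,
            rep_precision = rep_precision)
  fixed <- unlist(p[c("occ_intercept", "occ_beta_habitat",
                      "occ_beta_ecoregion", "rep_intercept",
                      "rep_beta_habitat", "rep_beta_ecoregion",
                      "det_intercepts", "det_beta_habitat")])
  if (!all(is.finite(fixed)))
    stop("all linear-predictor parameters must be finite", call. = FALSE)
  if (length(p$det_intercepts) != 3L || length(p$det_beta_habitat) != 3L)
    stop("det_intercepts and det_beta_habitat must have length 3 (p22, p23, p33)",
         call. = FALSE)
  if (!is.finite(p$occ_precision) || p$occ_precision <= 0 ||
      !is.finite(p$rep_precision) || p$rep_precision <= 0)
    stop("precisions must be strictly positive", call. = FALSE)
  if (length(p$occ_random_effects) != length(p$rep_random_effects))
    stop("random-effect vectors must have equal length", call. = FALSE)
  structure(p, class = "ms_params")
}

#' @export
print.ms_params <- function(x, ...) {
  cat("Multistate occupancy model parameters (logit scale)\n")
  cat(sprintf("  occupancy:    intercept % .3f  habitat % .3f  ecoregion % .3f\n",
              x$occ_intercept, x$occ_beta_habitat, x$occ_beta_ecoregion))
  cat(sprintf("  reproduction: intercept % .3f  habitat % .3f  ecoregion % .3f\n",
              x$rep_intercept, x$rep_beta_habitat, x$rep_beta_ecoregion))
  cat(sprintf("  detection intercepts (p22, p23, p33): %s\n",
              paste(sprintf("% .3f", x$det_intercepts), collapse = " ")))
  cat(sprintf("  detection habitat slopes:             %s\n",
              paste(sprintf("% .3f", x$det_beta_habitat), collapse = " ")))
  cat(sprintf("  random effects: %d sites, precision (occ, rep) = (%.3g, %.3g)\n",
              length(x$occ_random_effects), x$occ_precision, x$rep_precision))
  invisible(x)
}

#' Inverse-logit (logistic) transform
#'
#' Numerically stable for the full double range; strictly inside (0, 1)
#' up to floating-point resolution.
#'
#' @param x numeric vector on the logit scale.
#' @return probabilities in (0, 1).
#' @export
inv_logit <- function(x) stats::plogis(x)

# random-effect value for a site; params fitted without REs act as all-zero
re_at <- function(re, site) if (length(re) >= site) re[site] else 0

#' Occupancy and conditional reproduction probability at a site
#'
#' Evaluates the logit-linear submodels
#' `logit(psi_i) = a_occ + u_i + b_hab * habitat5km_std_i + b_eco * I(Sierra)`
#' and the analogous expression for `R_i` (cub occupancy given adult
#' occupancy), with `GreatBasin` as the reference ecoregion.
#'
#' @param cov a standardized [site_covariates()].
#' @param params an [ms_params()].
#' @param site site index (integer) or site id (character).
#' @return Named numeric vector `c(psi = ..., R = ...)`.
#' @export
occupancy_and_reproduction <- function(cov, params, site) {
  stopifnot(inherits(cov, "site_covariates"), inherits(params, "ms_params"))
  if (!isTRUE(cov$standardized))
    stop("covariates must be standardized (see standardize_covariates())",
         call. = FALSE)
  if (is.character(site)) site <- match(site, cov$site)
  if (is.na(site) || site < 1L || site > length(cov$site))
    stop("invalid site", call. = FALSE)
  eco <- ecoregion_indicator(cov)[site]
  lp_psi <- params$occ_intercept + re_at(params$occ_random_effects, site) +
    params$occ_beta_habitat * cov$habitat5km_std[site] +
    params$occ_beta_ecoregion * eco
  lp_r <- params$rep_intercept + re_at(params$rep_random_effects, site) +
    params$rep_beta_habitat * cov$habitat5km_std[site] +
    params$rep_beta_ecoregion * eco
  c(psi = inv_logit(lp_psi), R = inv_logit(lp_r))
}

#' Per-occasion detection probabilities at a site
#'
#' Each detection submodel is `logit(p) = a + b * habitat1km_std_i`.
#'
#' @inheritParams occupancy_and_reproduction
#' @return Named numeric vector `c(p22 = ..., p23 = ..., p33 = ...)`.
#' @export
detection_probs <- function(cov, params, site) {
  stopifnot(inherits(cov, "site_covariates"), inherits(params, "ms_params"))
  if (!isTRUE(cov$standardized))
    stop("covariates must be standardized (see standardize_covariates())",
         call. = FALSE)
  if (is.character(site)) site <- match(site, cov$site)
  if (is.na(site) || site < 1L || site > length(cov$site))
    stop("invalid site", call. = FALSE)
  x <- cov$habitat1km_std[site]
  p <- inv_logit(params$det_intercepts + params$det_beta_habitat * x)
  names(p) <- c("p22", "p23", "p33")
  p
}

#' Latent-state prior probabilities
#'
#' `(1 - psi, psi * (1 - R), psi * R)` over the states unoccupied /
#' adults-only / adults-with-cubs.
#'
#' @param psi,R probabilities.
#' @return length-3 probability vector summing to one.
#' @export
state_prob_vector <- function(psi, R) {
  stopifnot(psi >= 0, psi <= 1, R >= 0, R <= 1)
  c(1 - psi, psi * (1 - R), psi * R)
}

#' Observation (detection) matrix of the multinomial formulation
#'
#' Row-stochastic 3x3 matrix of `Pr(observe y | latent z)` for one occasion.
#' Rows index the latent state (unoccupied, adults-only, with-cubs), columns
#' the observation (0, 1, 2).  False positives cannot occur: an unoccupied
#' site always yields 0, and an adults-only site never yields a cub
#' observation.  Cubs may be missed (observed as 1 with probability `p23` or
#' as 0), the model's one-way misclassification.
#'
#' @param p22,p23,p33 per-occasion detection probabilities in `[0, 1]`,
#'   with `p23 + p33 <= 1`.  (The boundary values arise when a logit-scale
#'   parameter saturates; an exactly-zero detection probability makes the
#'   corresponding observation impossible.)
#' @return 3x3 numeric matrix.  Violation of `p23 + p33 <= 1` signals a
#'   classed error (`msoccu_constraint_violation`), which the sampler
#'   consumes as an automatic proposal rejection.
#' @export
observation_matrix <- function(p22, p23, p33) {
  stopifnot(p22 >= 0, p22 <= 1, p23 >= 0, p23 <= 1, p33 >= 0, p33 <= 1)
  if (p23 + p33 > 1)
    stop(structure(
      class = c("msoccu_constraint_violation", "error", "condition"),
      list(message = sprintf(
             "p23 + p33 = %.4f exceeds 1: multinomial detection constraint violated",
             p23 + p33),
           call = sys.call(-1))))
  matrix(c(1, 0, 0,
           1 - p22, p22, 0,
           1 - p23 - p33, p23, p33),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("unoccupied", "adults_only", "with_cubs"),
                         c("y0", "y1", "y2")))
}

#' Marginal log-likelihood of one site-year detection history
#'
#' Sums the latent state out of the joint:
#' `log sum_z phi[z] * prod_t theta[z, y_t]`, skipping missing occasions.
#' An all-missing history contributes exactly 0 (likelihood factor 1).
#'
#' @param y integer vector of observed states (`0/1/2`, `NA` = missing).
#' @param phi length-3 latent-state prior, e.g. [state_prob_vector()].
#' @param theta 3x3 observation matrix, e.g. [observation_matrix()].
#' @return log-likelihood (scalar); `-Inf` if no latent state can produce
#'   the observations.
#' @export
site_year_marginal_loglik <- function(y, phi, theta) {
  y <- y[!is.na(y)]
  if (!length(y)) return(0)
  lik <- 0
  for (z in 1:3) {
    lz <- phi[z] * prod(theta[z, y + 1L])
    lik <- lik + lz
  }
  log(lik)
}

#' Total marginal log-likelihood of a dataset
#'
#' Each site-year is an independent detection history sharing its site's
#' covariates and random effects; the total is the sum of the site-year
#' marginal log-likelihoods.
#'
#' @param data a [detection_history()].
#' @param cov a standardized [site_covariates()] aligned to `data`.
#' @param params an [ms_params()].
#' @return log-likelihood; `-Inf` when the detection constraint
#'   `p23 + p33 <= 1` fails at any site (rejection semantics).
#' @export
total_loglik <- function(data, cov, params) {
  stopifnot(inherits(data, "detection_history"))
  if (!identical(data$site_ids, cov$site))
    stop("detections and covariates are not aligned", call. = FALSE)
  ll <- 0
  for (i in seq_len(data$n_sites)) {
    pr <- occupancy_and_reproduction(cov, params, i)
    p <- detection_probs(cov, params, i)
    theta <- tryCatch(observation_matrix(p[1], p[2], p[3]),
                      msoccu_constraint_violation = function(e) NULL)
    if (is.null(theta)) return(-Inf)
    phi <- state_prob_vector(pr[["psi"]], pr[["R"]])
    for (j in seq_len(data$n_years))
      ll <- ll + site_year_marginal_loglik(data$y[i, j, ], phi, theta)
  }
  ll
}

#' Prior specification
#'
#' Diffuse priors in the convention of standard Bayesian occupancy-model
#' code: independent Normal(0, `fixed_sd`) on every fixed effect and
#' detection coefficient, and Uniform(0, `sd_upper`) on the random-effect
#' standard deviations (precision = sd^-2).
#'
#' @param fixed_sd prior standard deviation of fixed effects (default 10).
#' @param sd_upper upper bound of the uniform prior on random-effect
#'   standard deviations (default 10).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(fixed_sd = 10, sd_upper = 10) {
  stopifnot(fixed_sd > 0, sd_upper > 0)
  structure(list(fixed_sd = fixed_sd, sd_upper = sd_upper),
            class = "prior_spec")
}

#' Log prior density of a parameter set
#'
#' Normal(0, `fixed_sd`) on fixed effects and detection coefficients;
#' random effects are Normal(0, precision^-1/2) given their precision; the
#' implied random-effect standard deviations carry Uniform(0, `sd_upper`)
#' priors.
#'
#' @param params an [ms_params()].
#' @param prior a [prior_spec()].
#' @return log density; `-Inf` outside the prior support.
#' @export
log_prior <- function(params, prior = prior_spec()) {
  stopifnot(inherits(params, "ms_params"), inherits(prior, "prior_spec"))
  sd_occ <- 1 / sqrt(params$occ_precision)
  sd_rep <- 1 / sqrt(params$rep_precision)
  if (sd_occ >= prior$sd_upper || sd_rep >= prior$sd_upper) return(-Inf)
  fixed <- c(params$occ_intercept, params$occ_beta_habitat,
             params$occ_beta_ecoregion, params$rep_intercept,
             params$rep_beta_habitat, params$rep_beta_ecoregion,
             params$det_intercepts, params$det_beta_habitat)
  lp <- sum(stats::dnorm(fixed, 0, prior$fixed_sd, log = TRUE))
  lp <- lp - 2 * log(prior$sd_upper)  # uniform densities on the two sds
  if (length(params$occ_random_effects)) {
    lp <- lp +
      sum(stats::dnorm(params$occ_random_effects, 0, sd_occ, log = TRUE)) +
      sum(stats::dnorm(params$rep_random_effects, 0, sd_rep, log = TRUE))
  }
  lp
}
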