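#' MCMC configuration
#'
#' Defaults mirror a standard multistate-occupancy fitting protocol:
#' 3 chains of 200,000 iterations, the first 100,000 discarded as burn-in
#' and the remainder thinned by 40, leaving 2,500 retained draws per chain
#' (7,500 total).
#'
#' @param n_chains number of chains (default 3).
#' @param n_iterations iterations per chain (default 200000).
#' @param burn_in iterations discarded (default 100000); must be smaller
#'   than `n_iterations`.
#' @param thin thinning interval (default 40).
#' @param seed integer root seed; chain `c` uses a deterministic substream
#'   derived from `(seed, c)`.
#' @param proposal_scale initial random-walk standard deviation on the
#'   logit/log scale for every parameter (default 0.1).
#' @param adapt adapt proposal scales toward 35% acceptance during burn-in
#'   only (default `TRUE`); scales are frozen afterwards so the target
#'   distribution is untouched.
#' @param fix named list of parameters to hold fixed at given values
#'   (scalars by name, e.g. `occ_beta_habitat = 2.1`; `occ_re`/`rep_re`
#'   fix all random effects, a scalar is recycled).  Fixed parameters are
#'   never updated.
#' @param init optional named list of initial values (same names as `fix`),
#'   overriding the overdispersed random starts.
#' @param save_latent retain latent-state draws (needed for
#'   [expected_state_counts()]; default `TRUE`).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 200000,
                        burn_in = 100000, thin = 40, seed = 1,
                        proposal_scale = 0.1, adapt = TRUE,
                        fix = list(), init = list(), save_latent = TRUE) {
  stopifnot(n_chains >= 1, n_iterations >= 1, burn_in >= 0,
            burn_in < n_iterations, thin >= 1, proposal_scale > 0)
  bad <- setdiff(names(fix), c(fixed_param_names(), "sd_occ", "sd_rep",
                               "occ_re", "rep_re"))
  if (length(bad))
    stop("unknown parameter name(s) in fix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), proposal_scale = proposal_scale,
                 adapt = isTRUE(adapt), fix = fix, init = init,
                 save_latent = isTRUE(save_latent)),
            class = "mcmc_config")
}

#' Retained draws per chain implied by a configuration
#' @param config an [mcmc_config()].
#' @return integer number of retained draws per chain.
#' @export
retained_per_chain <- function(config) {
  (config$n_iterations - config$burn_in) %/% config$thin
}

fixed_param_names <- function() {
  c("occ_intercept", "occ_beta_habitat", "occ_beta_ecoregion",
    "rep_intercept", "rep_beta_habitat", "rep_beta_ecoregion",
    "det_intercept_p22", "det_intercept_p23", "det_intercept_p33",
    "det_beta_p22", "det_beta_p23", "det_beta_p33")
}

param_names <- function(site_ids) {
  c(fixed_param_names(), "sd_occ", "sd_rep",
    paste0("occ_re[", site_ids, "]"), paste0("rep_re[", site_ids, "]"))
}

# site-major per-site-year counts of active occasions with y = 0, 1, 2
sy_counts <- function(data) {
  S <- data$n_sites; J <- data$n_years
  counts <- matrix(0L, S * J, 3)
  sy_site <- integer(S * J); sy_year <- integer(S * J)
  r <- 0L
  for (i in seq_len(S)) for (j in seq_len(J)) {
    r <- r + 1L
    y <- data$y[i, j, ]
    y <- y[!is.na(y)]
    counts[r, ] <- c(sum(y == 0L), sum(y == 1L), sum(y == 2L))
    sy_site[r] <- i; sy_year[r] <- j
  }
  list(counts = counts, sy_site = sy_site, sy_year = sy_year)
}

# flat parameter vector <-> ms_params
params_to_vector <- function(params, n_sites) {
  re_o <- params$occ_random_effects
  re_r <- params$rep_random_effects
  if (!length(re_o)) re_o <- rep(0, n_sites)
  if (!length(re_r)) re_r <- rep(0, n_sites)
  c(params$occ_intercept, params$occ_beta_habitat, params$occ_beta_ecoregion,
    params$rep_intercept, params$rep_beta_habitat, params$rep_beta_ecoregion,
    params$det_intercepts, params$det_beta_habitat,
    1 / sqrt(params$occ_precision), 1 / sqrt(params$rep_precision),
    re_o, re_r)
}

vector_to_params <- function(v, n_sites) {
  ms_params(occ_intercept = v[1], occ_beta_habitat = v[2],
            occ_beta_ecoregion = v[3],
            rep_intercept = v[4], rep_beta_habitat = v[5],
            rep_beta_ecoregion = v[6],
            det_intercepts = v[7:9], det_beta_habitat = v[10:12],
            occ_precision = 1 / v[13]^2, rep_precision = 1 / v[14]^2,
            occ_random_effects = v[14 + seq_len(n_sites)],
            rep_random_effects = v[14 + n_sites + seq_len(n_sites)])
}

# apply config$fix / config$init entries onto a flat parameter vector
apply_named_values <- function(v, values, n_sites) {
  fp <- fixed_param_names()
  for (nm in names(values)) {
    val <- values[[nm]]
    if (nm %in% fp) v[match(nm, fp)] <- val
    else if (nm == "sd_occ") v[13] <- val
    else if (nm == "sd_rep") v[14] <- val
    else if (nm == "occ_re") v[14 + seq_len(n_sites)] <- val
    else if (nm == "rep_re") v[14 + n_sites + seq_len(n_sites)] <- val
  }
  v
}

update_masks <- function(fix, n_sites) {
  fp <- fixed_param_names()
  list(upd_fixed = !(fp %in% names(fix)),
       upd_sd_occ = !("sd_occ" %in% names(fix)),
       upd_sd_rep = !("sd_rep" %in% names(fix)),
       upd_occ_re = !("occ_re" %in% names(fix)),
       upd_rep_re = !("rep_re" %in% names(fix)))
}

#' Draw latent states from their exact full conditional
#'
#' For each site-year, `Pr(z | y, params)` is proportional to
#' `phi[z] * prod_t theta[z, y_t]` over active occasions; states
#' incompatible with the observations (e.g., any state other than
#' with-cubs when a cub was observed) get probability zero.  Uses R's RNG.
#'
#' @param data a [detection_history()].
#' @param cov standardized [site_covariates()] aligned to `data`.
#' @param params an [ms_params()].
#' @return integer matrix (site x year) of latent states in `{0, 1, 2}`.
#' @export
sample_latent_states <- function(data, cov, params) {
  z <- matrix(NA_integer_, data$n_sites, data$n_years,
              dimnames = list(data$site_ids, data$year_labels))
  for (i in seq_len(data$n_sites)) {
    pr <- occupancy_and_reproduction(cov, params, i)
    p <- detection_probs(cov, params, i)
    theta <- observation_matrix(p[1], p[2], p[3])
    phi <- state_prob_vector(pr[["psi"]], pr[["R"]])
    for (j in seq_len(data$n_years)) {
      y <- data$y[i, j, ]
      y <- y[!is.na(y)]
      w <- vapply(1:3, function(zz) phi[zz] * prod(theta[zz, y + 1L]),
                  numeric(1))
      z[i, j] <- sample.int(3L, 1L, prob = w) - 1L
    }
  }
  z
}

#' One Metropolis-within-Gibbs parameter sweep with latent states held fixed
#'
#' Performs a single blockwise random-walk Metropolis pass over all
#' non-fixed parameters against the complete-data posterior given `z`.
#' Detailed balance is preserved; proposals violating the detection
#' constraint `p23 + p33 <= 1` at any site are rejected outright.
#'
#' @inheritParams sample_latent_states
#' @param z integer matrix (site x year) of latent states.
#' @param config an [mcmc_config()] (its `proposal_scale` and `fix` are
#'   used).
#' @param prior a [prior_spec()].
#' @return Updated [ms_params()].
#' @export
update_parameters <- function(data, cov, params, z,
                              config = mcmc_config(), prior = prior_spec()) {
  prep <- sy_counts(data)
  S <- data$n_sites
  v <- params_to_vector(params, S)
  v <- apply_named_values(v, config$fix, S)
  zz <- as.integer(t(z))  # site-major site-year order
  masks <- update_masks(config$fix, S)
  res <- mcmc_chain_cpp(prep$counts, S, data$n_years,
                        cov$habitat5km_std, cov$habitat1km_std,
                        ecoregion_indicator(cov),
                        prior$fixed_sd, prior$sd_upper,
                        v, zz,
                        masks$upd_fixed, masks$upd_sd_occ, masks$upd_sd_rep,
                        masks$upd_occ_re, masks$upd_rep_re, FALSE,
                        rep(config$proposal_scale, 14 + 2 * S),
                        1L, 0L, 1L, FALSE, FALSE)
  vector_to_params(res$final_par, S)
}

#' Initial chain states
#'
#' Latent states start at the maximum state ever observed at each
#' site-year (the only assignment guaranteed compatible with the data);
#' all-missing site-years draw their state from the initial state prior.
#' Parameters take overdispersed random starts, distinct per chain and
#' fully determined by the seed; entries of `config$fix`/`config$init`
#' override them.
#'
#' @inheritParams sample_latent_states
#' @param config an [mcmc_config()].
#' @param prior a [prior_spec()].
#' @return A list with one element per chain: `list(params, z)` where
#'   `params` is a flat named vector and `z` a site-major integer vector.
#' @export
initialize_chains <- function(data, cov, config = mcmc_config(),
                              prior = prior_spec()) {
  prep <- sy_counts(data)
  S <- data$n_sites
  nsy <- nrow(prep$counts)
  z_obs <- integer(nsy)
  for (r in seq_len(nsy)) {
    if (prep$counts[r, 3] > 0L) z_obs[r] <- 2L
    else if (prep$counts[r, 2] > 0L) z_obs[r] <- 1L
    else if (prep$counts[r, 1] > 0L) z_obs[r] <- 0L
    else z_obs[r] <- NA_integer_  # all missing
  }
  lapply(seq_len(config$n_chains), function(ch) {
    set.seed(chain_seed(config$seed, ch))
    v <- c(stats::rnorm(12, 0, 1.5),
           stats::runif(2, 0.5, 2))
    sds <- v[13:14]
    v <- c(v, stats::rnorm(S, 0, sds[1]), stats::rnorm(S, 0, sds[2]))
    v <- apply_named_values(v, config$fix, S)
    v <- apply_named_values(v, config$init, S)
    # ensure the detection constraint holds at the start
    tries <- 0
    repeat {
      p23 <- inv_logit(v[8] + v[11] * cov$habitat1km_std)
      p33 <- inv_logit(v[9] + v[12] * cov$habitat1km_std)
      if (all(p23 + p33 < 1)) break
      tries <- tries + 1
      if (tries > 200)
        stop("could not find initial detection parameters satisfying ",
             "p23 + p33 <= 1", call. = FALSE)
      v[7:12] <- stats::rnorm(6, 0, 1)
      v <- apply_named_values(v, config$fix, S)
      v <- apply_named_values(v, config$init, S)
    }
    z <- z_obs
    if (anyNA(z)) {
      for (r in which(is.na(z))) {
        i <- prep$sy_site[r]
        psi <- inv_logit(v[1] + v[14 + i] +
                           v[2] * cov$habitat5km_std[i] +
                           v[3] * ecoregion_indicator(cov)[i])
        R <- inv_logit(v[4] + v[14 + S + i] +
                         v[5] * cov$habitat5km_std[i] +
                         v[6] * ecoregion_indicator(cov)[i])
        z[r] <- sample.int(3L, 1L, prob = state_prob_vector(psi, R)) - 1L
      }
    }
    names(v) <- param_names(data$site_ids)
    list(params = v, z = z)
  })
}

chain_seed <- function(seed, chain) {
  as.integer((as.numeric(seed) * 1009 + chain * 7919) %% 2147483629)
}

#' Fit the multistate occupancy model by MCMC
#'
#' Alternates an exact Gibbs draw of every site-year latent state with
#' blockwise random-walk Metropolis updates of all parameters (fixed
#' effects, detection coefficients, site random effects, random-effect
#' standard deviations on the log scale).  Proposal scales adapt toward
#' 35% acceptance during burn-in only.  Fully reproducible from
#' `config$seed`.
#'
#' @inheritParams sample_latent_states
#' @param config an [mcmc_config()].
#' @param prior a [prior_spec()].
#' @param verbose print per-chain progress (default `FALSE`).
#' @return An object of class `posterior_draws`: retained draws as a
#'   `chain x draw x parameter` array, optional latent-state draws
#'   (`chain x draw x site-year`), acceptance rates, and the metadata
#'   needed for prediction (standardization constants, site/year labels).
#' @export
run_mcmc <- function(data, cov, config = mcmc_config(),
                     prior = prior_spec(), verbose = FALSE) {
  stopifnot(inherits(data, "detection_history"),
            inherits(cov, "site_covariates"),
            inherits(config, "mcmc_config"))
  if (!isTRUE(cov$standardized))
    stop("covariates must be standardized before fitting", call. = FALSE)
  if (!identical(data$site_ids, cov$site))
    stop("detections and covariates are not aligned", call. = FALSE)
  if (stats::sd(ecoregion_indicator(cov)) == 0 &&
      !("occ_beta_ecoregion" %in% names(config$fix) &&
        "rep_beta_ecoregion" %in% names(config$fix)))
    stop("ecoregion is constant across sites; its effect is not ",
         "identifiable -- fix occ_beta_ecoregion and rep_beta_ecoregion ",
         "or drop the term", call. = FALSE)

  prep <- sy_counts(data)
  S <- data$n_sites
  n_par <- 14 + 2 * S
  pn <- param_names(data$site_ids)
  inits <- initialize_chains(data, cov, config, prior)
  masks <- update_masks(config$fix, S)
  n_kept <- retained_per_chain(config)
  if (n_kept < 1) stop("configuration retains no draws", call. = FALSE)

  draws <- array(NA_real_, c(config$n_chains, n_kept, n_par),
                 dimnames = list(NULL, NULL, pn))
  latent <- if (config$save_latent)
    array(NA_integer_, c(config$n_chains, n_kept, nrow(prep$counts)))
  else NULL
  accept <- matrix(NA_real_, config$n_chains, n_par,
                   dimnames = list(NULL, pn))

  for (ch in seq_len(config$n_chains)) {
    ini <- inits[[ch]]
    lp0 <- complete_log_post_cpp(prep$counts, S, data$n_years,
                                 cov$habitat5km_std, cov$habitat1km_std,
                                 ecoregion_indicator(cov),
                                 prior$fixed_sd, prior$sd_upper,
                                 ini$params, ini$z)
    if (!is.finite(lp0))
      stop("non-finite log posterior at initialization (chain ", ch,
           "); check that fixed/initial values lie in the prior support ",
           "and satisfy p23 + p33 <= 1", call. = FALSE)
    set.seed(chain_seed(config$seed, ch) + 1L)
    if (verbose)
      message(sprintf("chain %d: %d iterations (burn-in %d, thin %d)",
                      ch, config$n_iterations, config$burn_in, config$thin))
    res <- mcmc_chain_cpp(prep$counts, S, data$n_years,
                          cov$habitat5km_std, cov$habitat1km_std,
                          ecoregion_indicator(cov),
                          prior$fixed_sd, prior$sd_upper,
                          ini$params, ini$z,
                          masks$upd_fixed, masks$upd_sd_occ,
                          masks$upd_sd_rep,
                          masks$upd_occ_re, masks$upd_rep_re, TRUE,
                          rep(config$proposal_scale, n_par),
                          config$n_iterations, config$burn_in, config$thin,
                          config$adapt, config$save_latent)
    draws[ch, , ] <- res$draws
    if (config$save_latent) latent[ch, , ] <- res$latent
    accept[ch, ] <- res$accept
  }

  structure(
    list(draws = draws, parameter_names = pn, latent_state_draws = latent,
         accept = accept, config = config, prior = prior,
         site_ids = data$site_ids, year_labels = data$year_labels,
         n_sites = S, n_years = data$n_years,
         sy_site = prep$sy_site, sy_year = prep$sy_year,
         standardization = cov$standardization,
         covariates = cov),
    class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior draws: %d chains x %d retained draws x %d parameters\n",
              d[1], d[2], d[3]))
  cat(sprintf("  sites: %d, years: %d, latent states %s\n", x$n_sites,
              x$n_years,
              if (is.null(x$latent_state_draws)) "not retained" else "retained"))
  invisible(x)
}

#' Pool retained draws across chains
#' @param x a `posterior_draws` object.
#' @param ... unused.
#' @return matrix `(chains * draws) x parameters`.
#' @export
as.matrix.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  out <- matrix(aperm(x$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(out) <- x$parameter_names
  out
}
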