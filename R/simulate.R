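#' Simulation design for synthetic camera-trap studies
#'
#' Defaults emulate a 100-site, 3-season design with 9 monthly occasions
#' per season, 11 sites in the SierraNevada ecoregion and 89 in the
#' GreatBasin.  Habitat proportions are drawn per ecoregion from Beta
#' distributions (GreatBasin `Beta(2, 2)`, spanning the full [0, 1]
#' gradient; SierraNevada `Beta(5, 2)`, higher on average); the fine-scale
#' (1 km) proportion is coupled to the coarse (5 km) one through a
#' Gaussian copula with the given latent correlation.  The default
#' missingness calendar mimics a mid-season first-year deployment: in year
#' 1 all sites are inactive before `first_year_start`; later years are
#' fully active.  An additional per-occasion missing probability can model
#' camera failure.
#'
#' @param n_sites,n_sierra,n_years,n_occasions study dimensions.
#' @param gb_beta,sn_beta `c(shape1, shape2)` of the habitat Beta
#'   distribution in each ecoregion.
#' @param habitat1km_correlation latent (copula) correlation between the
#'   1 km and 5 km habitat proportions, in `[-1, 1]`.
#' @param first_year_start first active occasion in year 1 (default 3).
#' @param missing_prob independent per-occasion inactive probability on
#'   top of the calendar (default 0).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(n_sites = 100, n_sierra = 11, n_years = 3,
                              n_occasions = 9,
                              gb_beta = c(2, 2), sn_beta = c(5, 2),
                              habitat1km_correlation = 0.8,
                              first_year_start = 3, missing_prob = 0) {
  stopifnot(n_sites >= 1, n_sierra >= 0, n_sierra <= n_sites,
            n_years >= 1, n_occasions >= 1,
            habitat1km_correlation >= -1, habitat1km_correlation <= 1,
            first_year_start >= 1, first_year_start <= n_occasions + 1,
            missing_prob >= 0, missing_prob < 1)
  structure(list(n_sites = as.integer(n_sites),
                 n_sierra = as.integer(n_sierra),
                 n_years = as.integer(n_years),
                 n_occasions = as.integer(n_occasions),
                 gb_beta = gb_beta, sn_beta = sn_beta,
                 habitat1km_correlation = habitat1km_correlation,
                 first_year_start = as.integer(first_year_start),
                 missing_prob = missing_prob),
            class = "simulation_design")
}

#' Default generating parameters for simulation fixtures
#'
#' Slopes sit at field-realistic values for a range-margin bear
#' population: strong positive ecoregion contrasts (5.8 occupancy, 3.3
#' reproduction), positive coarse-habitat slopes (2.1, 1.7), a modest
#' fine-habitat effect on adult detection (0.8) and essentially none on
#' the two cub-related detection probabilities (0.0, -0.1).  Random-effect
#' precisions are 0.45 (occupancy) and 1.97 (reproduction).  Intercepts
#' are chosen to give plausible baseline rates on the probability scale:
#' reference-ecoregion occupancy near 0.39 and conditional reproduction
#' near 0.32 at average habitat, and baseline monthly detection
#' probabilities near 0.15 (adults alone), 0.48 (adults when cubs
#' present) and 0.23 (cubs).
#'
#' @return An [ms_params()] (random effects empty; they are drawn at
#'   simulation time from the stated precisions).
#' @export
default_truth <- function() {
  ms_params(occ_intercept = -0.45, occ_beta_habitat = 2.1,
            occ_beta_ecoregion = 5.8,
            rep_intercept = -0.75, rep_beta_habitat = 1.7,
            rep_beta_ecoregion = 3.3,
            det_intercepts = c(-1.7, -0.08, -1.2),
            det_beta_habitat = c(0.8, 0.0, -0.1),
            occ_precision = 0.45, rep_precision = 1.97)
}

#' Generate site covariates under a simulation design
#'
#' @param design a [simulation_design()].
#' @return A [site_covariates()] (raw scale, not yet standardized).  Uses
#'   R's RNG; seed with [set.seed()] for reproducibility.
#' @export
generate_covariates <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  n <- design$n_sites
  eco <- rep(c("SierraNevada", "GreatBasin"),
             c(design$n_sierra, n - design$n_sierra))
  rho <- design$habitat1km_correlation
  z5 <- stats::rnorm(n)
  z1 <- rho * z5 + sqrt(1 - rho^2) * stats::rnorm(n)
  sh <- function(e) if (e == "SierraNevada") design$sn_beta else design$gb_beta
  h5 <- h1 <- numeric(n)
  for (i in seq_len(n)) {
    s <- sh(eco[i])
    h5[i] <- stats::qbeta(stats::pnorm(z5[i]), s[1], s[2])
    h1[i] <- stats::qbeta(stats::pnorm(z1[i]), s[1], s[2])
  }
  site_covariates(sprintf("s%03d", seq_len(n)), h5, h1, eco)
}

#' Simulate a multistate detection dataset from known parameters
#'
#' Runs the generative model forward: site random effects are drawn from
#' `Normal(0, precision^-1)` (unless supplied in `truth`), per-site
#' `psi_i`, `R_i` and detection probabilities are computed, a latent state
#' is drawn per site-year from `(1 - psi, psi (1 - R), psi R)`, and each
#' active occasion draws an observation from the corresponding row of the
#' observation matrix.  The no-false-positive structure holds by
#' construction.
#'
#' @param truth an [ms_params()]; if its random-effect vectors are empty
#'   they are drawn from the stated precisions.
#' @param design a [simulation_design()].
#' @param covariates optionally, a fixed [site_covariates()] to condition
#'   on (default: drawn from the design).
#' @return A list with class `synthetic_dataset`: `history`
#'   ([detection_history()]), `covariates` (standardized
#'   [site_covariates()]), and `truth` — the full generating record
#'   (`params` with realized random effects, latent state matrix `z`,
#'   per-site `psi`, `R`, `p22`, `p23`, `p33`).  Uses R's RNG.
#' @export
simulate_dataset <- function(truth = default_truth(),
                             design = simulation_design(),
                             covariates = NULL) {
  stopifnot(inherits(truth, "ms_params"), inherits(design, "simulation_design"))
  n <- design$n_sites
  cov <- if (is.null(covariates)) generate_covariates(design) else covariates
  stopifnot(length(cov$site) == n)
  if (!isTRUE(cov$standardized)) cov <- standardize_covariates(cov)

  re_o <- truth$occ_random_effects
  re_r <- truth$rep_random_effects
  if (!length(re_o)) re_o <- stats::rnorm(n, 0, 1 / sqrt(truth$occ_precision))
  if (!length(re_r)) re_r <- stats::rnorm(n, 0, 1 / sqrt(truth$rep_precision))
  params <- truth
  params$occ_random_effects <- re_o
  params$rep_random_effects <- re_r

  eco <- ecoregion_indicator(cov)
  psi <- inv_logit(params$occ_intercept + re_o +
                     params$occ_beta_habitat * cov$habitat5km_std +
                     params$occ_beta_ecoregion * eco)
  R <- inv_logit(params$rep_intercept + re_r +
                   params$rep_beta_habitat * cov$habitat5km_std +
                   params$rep_beta_ecoregion * eco)
  p22 <- inv_logit(params$det_intercepts[1] +
                     params$det_beta_habitat[1] * cov$habitat1km_std)
  p23 <- inv_logit(params$det_intercepts[2] +
                     params$det_beta_habitat[2] * cov$habitat1km_std)
  p33 <- inv_logit(params$det_intercepts[3] +
                     params$det_beta_habitat[3] * cov$habitat1km_std)
  if (any(p23 + p33 > 1))
    stop("invalid truth: p23 + p33 > 1 at site ",
         cov$site[which(p23 + p33 > 1)[1]], call. = FALSE)

  active <- array(TRUE, c(n, design$n_years, design$n_occasions))
  if (design$first_year_start > 1)
    active[, 1, seq_len(design$first_year_start - 1L)] <- FALSE
  if (design$missing_prob > 0) {
    drop <- array(stats::runif(length(active)) < design$missing_prob,
                  dim(active))
    active <- active & !drop
  }

  z <- matrix(NA_integer_, n, design$n_years)
  y <- array(NA_integer_, c(n, design$n_years, design$n_occasions))
  for (i in seq_len(n)) {
    phi <- state_prob_vector(psi[i], R[i])
    theta <- rbind(c(1, 0, 0),
                   c(1 - p22[i], p22[i], 0),
                   c(1 - p23[i] - p33[i], p23[i], p33[i]))
    for (j in seq_len(design$n_years)) {
      z[i, j] <- sample.int(3L, 1L, prob = phi) - 1L
      for (t in seq_len(design$n_occasions)) {
        if (!active[i, j, t]) next
        y[i, j, t] <- sample.int(3L, 1L, prob = theta[z[i, j] + 1L, ]) - 1L
      }
    }
  }
  history <- detection_history(y, site_ids = cov$site,
                               year_labels = as.character(
                                 2017L + seq_len(design$n_years)))
  structure(list(history = history, covariates = cov,
                 truth = list(params = params, z = z, psi = psi, R = R,
                              p22 = p22, p23 = p23, p33 = p33)),
            class = "synthetic_dataset")
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a dataset at the given truth and design, fits it
#' with [run_mcmc()], and records, per fixed effect: posterior mean, bias,
#' whether the central 95% credible interval covers the truth, sign
#' agreement of the posterior mean with the truth, and Rhat.  Replicates
#' whose fixed effects have not all converged (Rhat < 1.1) are flagged in
#' the per-replicate table rather than dropped.
#'
#' @param truth an [ms_params()] (fixed effects are the recovery targets).
#' @param design a [simulation_design()].
#' @param fit_config an [mcmc_config()]; replicate `r` fits with seed
#'   `fit_config$seed + r`.
#' @param n_replicates number of simulate-fit cycles.
#' @param parameters fixed-effect names to score (default: the six
#'   occupancy/reproduction fixed effects).
#' @param verbose print one line per replicate.
#' @return list with `per_replicate` (long data.frame: replicate,
#'   parameter, truth, estimate, bias, covered, sign_match, rhat,
#'   all_converged) and `summary` (per-parameter mean bias, coverage and
#'   sign-agreement rates with Monte-Carlo standard errors).
#' @export
recovery_experiment <- function(truth = default_truth(),
                                design = simulation_design(),
                                fit_config = mcmc_config(),
                                n_replicates = 20,
                                parameters = c("occ_intercept",
                                               "occ_beta_habitat",
                                               "occ_beta_ecoregion",
                                               "rep_intercept",
                                               "rep_beta_habitat",
                                               "rep_beta_ecoregion"),
                                verbose = FALSE) {
  stopifnot(n_replicates >= 1)
  truth_vals <- c(occ_intercept = truth$occ_intercept,
                  occ_beta_habitat = truth$occ_beta_habitat,
                  occ_beta_ecoregion = truth$occ_beta_ecoregion,
                  rep_intercept = truth$rep_intercept,
                  rep_beta_habitat = truth$rep_beta_habitat,
                  rep_beta_ecoregion = truth$rep_beta_ecoregion,
                  det_intercept_p22 = truth$det_intercepts[1],
                  det_intercept_p23 = truth$det_intercepts[2],
                  det_intercept_p33 = truth$det_intercepts[3],
                  det_beta_p22 = truth$det_beta_habitat[1],
                  det_beta_p23 = truth$det_beta_habitat[2],
                  det_beta_p33 = truth$det_beta_habitat[3])
  stopifnot(all(parameters %in% names(truth_vals)))
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- fit_config
    cfg$seed <- fit_config$seed + r
    set.seed(chain_seed(cfg$seed, 0L))
    sim <- simulate_dataset(truth, design)
    fit <- run_mcmc(sim$history, sim$covariates, cfg)
    summ <- summarize_posterior(fit, parameters)
    all_conv <- all(summ$rhat < 1.1, na.rm = TRUE)
    rows[[r]] <- data.frame(
      replicate = r, parameter = summ$parameter,
      truth = unname(truth_vals[summ$parameter]),
      estimate = summ$mean,
      bias = summ$mean - unname(truth_vals[summ$parameter]),
      covered = summ$q2.5 <= truth_vals[summ$parameter] &
        truth_vals[summ$parameter] <= summ$q97.5,
      sign_match = sign(summ$mean) == sign(truth_vals[summ$parameter]),
      rhat = summ$rhat, all_converged = all_conv,
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("replicate %d/%d done (converged: %s)", r,
                      n_replicates, all_conv))
  }
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$parameter), function(d) {
    n <- nrow(d)
    data.frame(parameter = d$parameter[1],
               mean_bias = mean(d$bias),
               bias_mcse = stats::sd(d$bias) / sqrt(n),
               coverage = mean(d$covered),
               coverage_mcse = sqrt(mean(d$covered) *
                                      (1 - mean(d$covered)) / n),
               sign_agreement = mean(d$sign_match),
               n_replicates = n, stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(per_replicate = per_rep, summary = agg)
}
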