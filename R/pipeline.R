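#' Persist posterior draws as plain-text files
#'
#' Writes `draws.csv` (one row per chain x retained draw, one column per
#' parameter), optionally `latent.csv` (latent states per site-year), and
#' `meta.json` (labels, standardization constants, dimensions) to a
#' directory, so that prediction and diagnosis can run in a later session.
#'
#' @param fit a `posterior_draws` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_posterior_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "posterior_draws"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(fit$draws)
  idx <- expand.grid(draw = seq_len(d[2]), chain = seq_len(d[1]))
  m <- as.matrix(fit)
  utils::write.csv(cbind(idx[c("chain", "draw")], as.data.frame(m)),
                   file.path(dir, "draws.csv"), row.names = FALSE)
  if (!is.null(fit$latent_state_draws)) {
    ld <- dim(fit$latent_state_draws)
    lm <- matrix(aperm(fit$latent_state_draws, c(2, 1, 3)),
                 ld[1] * ld[2], ld[3])
    colnames(lm) <- paste0("sy", seq_len(ld[3]))
    utils::write.csv(cbind(idx[c("chain", "draw")], as.data.frame(lm)),
                     file.path(dir, "latent.csv"), row.names = FALSE)
  }
  meta <- list(parameter_names = fit$parameter_names,
               site_ids = fit$site_ids, year_labels = fit$year_labels,
               n_sites = fit$n_sites, n_years = fit$n_years,
               n_chains = d[1], n_draws = d[2],
               sy_site = fit$sy_site, sy_year = fit$sy_year,
               standardization = lapply(fit$standardization, as.list))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reload posterior draws written by [save_posterior_draws()]
#' @param dir directory containing `draws.csv` and `meta.json`.
#' @return A `posterior_draws` object (without acceptance rates or the
#'   original covariate table).
#' @export
load_posterior_draws <- function(dir) {
  dp <- file.path(dir, "draws.csv")
  mp <- file.path(dir, "meta.json")
  if (!file.exists(dp) || !file.exists(mp))
    stop("no stored draws found in ", dir, call. = FALSE)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  df <- utils::read.csv(dp, check.names = FALSE)
  n_chains <- meta$n_chains; n_draws <- meta$n_draws
  pn <- meta$parameter_names
  m <- as.matrix(df[pn])
  draws <- aperm(array(m, c(n_draws, n_chains, length(pn))), c(2, 1, 3))
  dimnames(draws) <- list(NULL, NULL, pn)
  latent <- NULL
  lp <- file.path(dir, "latent.csv")
  if (file.exists(lp)) {
    ldf <- utils::read.csv(lp, check.names = FALSE)
    lm <- as.matrix(ldf[grep("^sy", names(ldf))])
    latent <- aperm(array(as.integer(lm),
                          c(n_draws, n_chains, ncol(lm))), c(2, 1, 3))
  }
  std <- lapply(meta$standardization, function(s)
    c(mean = s$mean, sd = s$sd))
  structure(
    list(draws = draws, parameter_names = pn, latent_state_draws = latent,
         accept = NULL, config = NULL, prior = NULL,
         site_ids = meta$site_ids, year_labels = as.character(meta$year_labels),
         n_sites = meta$n_sites, n_years = meta$n_years,
         sy_site = meta$sy_site, sy_year = meta$sy_year,
         standardization = std, covariates = NULL),
    class = "posterior_draws")
}

#' Pipeline command: simulate a dataset to files
#'
#' Writes `detections.csv` (long dialect), `covariates.csv` and
#' `truth.json` (generating parameters and realized latent states) under
#' `out_dir`, reproducibly from `seed`.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the list of written paths.
#' @export
cmd_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(chain_seed(cfg$seed, 0L))
  sim <- simulate_dataset(default_truth(), as_simulation_design(cfg))
  dpath <- file.path(cfg$out_dir, "detections.csv")
  cpath <- file.path(cfg$out_dir, "covariates.csv")
  tpath <- file.path(cfg$out_dir, "truth.json")
  write_detections(sim$history, dpath, dialect = cfg$dialect)
  write_covariates(sim$covariates, cpath)
  tr <- sim$truth
  jsonlite::write_json(
    list(params = unclass(tr$params), z = tr$z, psi = tr$psi, R = tr$R,
         p22 = tr$p22, p23 = tr$p23, p33 = tr$p33),
    tpath, auto_unbox = TRUE, digits = NA)
  log_to(cfg, "simulate.log",
         c(provenance_lines(cfg),
           sprintf("simulated %d sites x %d years x %d occasions",
                   cfg$n_sites, cfg$n_years, cfg$n_occasions),
           paste("wrote:", dpath), paste("wrote:", cpath),
           paste("wrote:", tpath)))
  invisible(list(detections = dpath, covariates = cpath, truth = tpath))
}

#' Pipeline command: fit the model to files
#'
#' Reads the detection and covariate CSVs named in the config, validates
#' and standardizes, runs [run_mcmc()], and writes `summary.csv` (mean,
#' 95% CrI and Rhat per parameter), the stored draws
#' (see [save_posterior_draws()]) and `fit.log` under `out_dir`.
#'
#' @param cfg a [run_config()].
#' @return the `posterior_draws` object, invisibly.
#' @export
cmd_fit <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$detections) || is.null(cfg$covariates))
    stop("fit mode requires 'detections' and 'covariates' paths",
         call. = FALSE)
  data <- read_detections(cfg$detections, dialect = cfg$dialect)
  cov <- standardize_covariates(read_covariates(cfg$covariates, data))
  fit <- run_mcmc(data, cov, as_mcmc_config(cfg), as_prior_spec(cfg),
                  verbose = cfg$verbosity > 0)
  summ <- summarize_posterior(fit)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summ, file.path(cfg$out_dir, "summary.csv"),
                   row.names = FALSE)
  save_posterior_draws(fit, cfg$out_dir)
  fixed <- summ[summ$parameter %in% c(fixed_param_names(),
                                      "sd_occ", "sd_rep"), ]
  log_to(cfg, "fit.log",
         c(provenance_lines(cfg),
           sprintf("retained %d draws per chain (%d total)",
                   retained_per_chain(as_mcmc_config(cfg)),
                   cfg$n_chains * retained_per_chain(as_mcmc_config(cfg))),
           sprintf("max Rhat over fixed effects: %.4f",
                   max(fixed$rhat, na.rm = TRUE)),
           sprintf("unconverged parameters (Rhat >= 1.1): %d",
                   sum(!summ$converged, na.rm = TRUE))))
  invisible(fit)
}

#' Pipeline command: derived predictions from stored draws
#'
#' Loads draws written by [cmd_fit()] from `out_dir` and writes
#' `curves.csv` (occupancy and conditional-reproduction response curves
#' over a habitat grid for both ecoregions, with 95% credible bands),
#' `state_counts.csv` (posterior occupancy-state counts per year), and —
#' if the config names a `prediction_grid` CSV — `grid_predictions.csv`.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the list of written tables.
#' @export
cmd_predict <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  fit <- load_posterior_draws(cfg$out_dir)
  hab <- seq(0, 1, length.out = cfg$curve_points)
  curves <- rbind(
    cbind(predict_psi_R(fit, hab, "GreatBasin", policy = cfg$predict_policy)),
    cbind(predict_psi_R(fit, hab, "SierraNevada",
                        policy = cfg$predict_policy)))
  utils::write.csv(curves, file.path(cfg$out_dir, "curves.csv"),
                   row.names = FALSE)
  counts <- NULL
  if (!is.null(fit$latent_state_draws)) {
    counts <- do.call(rbind, lapply(fit$year_labels, function(yl)
      cbind(year = yl, expected_state_counts(fit, yl))))
    utils::write.csv(counts, file.path(cfg$out_dir, "state_counts.csv"),
                     row.names = FALSE)
  }
  gridp <- NULL
  if (!is.null(cfg$prediction_grid)) {
    grid <- utils::read.csv(cfg$prediction_grid)
    gridp <- predict_grid(fit, grid, policy = cfg$predict_policy)
    utils::write.csv(gridp, file.path(cfg$out_dir, "grid_predictions.csv"),
                     row.names = FALSE)
  }
  log_to(cfg, "predict.log",
         c(provenance_lines(cfg),
           sprintf("curve table: %d rows", nrow(curves)),
           sprintf("state counts: %s",
                   if (is.null(counts)) "skipped (no latent draws)"
                   else paste(nrow(counts), "rows"))))
  invisible(list(curves = curves, state_counts = counts, grid = gridp))
}

#' Pipeline command: convergence report from stored draws
#'
#' @param cfg a [run_config()].
#' @return the summary data.frame, invisibly.
#' @export
cmd_diagnose <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  fit <- load_posterior_draws(cfg$out_dir)
  summ <- summarize_posterior(fit)
  utils::write.csv(summ[c("parameter", "rhat", "converged")],
                   file.path(cfg$out_dir, "rhat_report.csv"),
                   row.names = FALSE)
  log_to(cfg, "diagnose.log",
         c(provenance_lines(cfg),
           sprintf("max Rhat: %.4f",
                   max(summ$rhat, na.rm = TRUE)),
           sprintf("parameters with Rhat >= 1.1: %d",
                   sum(!summ$converged, na.rm = TRUE))))
  invisible(summ)
}
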