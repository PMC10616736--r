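#' Run configuration for the command pipeline
#'
#' A flat `key = value` text format (one pair per line, `#` comments)
#' configures the simulate / fit / predict / diagnose pipeline.  Unknown
#' keys are rejected.  Recognized keys and defaults are those of
#' [run_config()].
#'
#' @param path path to a key-value config file.
#' @param overrides named list applied after the file (e.g., from
#'   command-line flags).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln,
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  for (nm in names(overrides)) kv[[nm]] <- overrides[[nm]]
  do.call(run_config, kv)
}

#' @rdname read_run_config
#' @param detections,covariates input CSV paths (fit mode).
#' @param out_dir output directory.
#' @param dialect detection-file dialect, `long` or `wide`.
#' @param n_chains,n_iterations,burn_in,thin,seed,proposal_scale,adapt,save_latent
#'   MCMC settings, see [mcmc_config()].
#' @param prior_fixed_sd,prior_sd_upper prior settings, see [prior_spec()].
#' @param n_sites,n_sierra,n_years,n_occasions,habitat1km_correlation,first_year_start,missing_prob
#'   simulation design (simulate mode), see [simulation_design()].
#' @param curve_points number of habitat values on the prediction curve grid.
#' @param predict_policy random-effect policy for predictions
#'   (`typical` or `marginal`).
#' @param prediction_grid optional CSV of `(habitat5km, ecoregion)` cells.
#' @param verbosity 0 = quiet, 1 = progress messages.
#' @export
run_config <- function(detections = NULL, covariates = NULL,
                       out_dir = ".", dialect = "long",
                       n_chains = 3, n_iterations = 200000,
                       burn_in = 100000, thin = 40, seed = 1,
                       proposal_scale = 0.1, adapt = TRUE,
                       save_latent = TRUE,
                       prior_fixed_sd = 10, prior_sd_upper = 10,
                       n_sites = 100, n_sierra = 11, n_years = 3,
                       n_occasions = 9, habitat1km_correlation = 0.8,
                       first_year_start = 3, missing_prob = 0,
                       curve_points = 50, predict_policy = "typical",
                       prediction_grid = NULL, verbosity = 1) {
  num <- function(x) if (is.character(x)) as.numeric(x) else x
  lgl <- function(x) if (is.character(x))
    toupper(x) %in% c("TRUE", "T", "YES", "1") else isTRUE(x)
  cfg <- list(detections = detections, covariates = covariates,
              out_dir = out_dir, dialect = match.arg(dialect,
                                                     c("long", "wide")),
              n_chains = num(n_chains), n_iterations = num(n_iterations),
              burn_in = num(burn_in), thin = num(thin), seed = num(seed),
              proposal_scale = num(proposal_scale), adapt = lgl(adapt),
              save_latent = lgl(save_latent),
              prior_fixed_sd = num(prior_fixed_sd),
              prior_sd_upper = num(prior_sd_upper),
              n_sites = num(n_sites), n_sierra = num(n_sierra),
              n_years = num(n_years), n_occasions = num(n_occasions),
              habitat1km_correlation = num(habitat1km_correlation),
              first_year_start = num(first_year_start),
              missing_prob = num(missing_prob),
              curve_points = num(curve_points),
              predict_policy = match.arg(predict_policy,
                                         c("typical", "marginal")),
              prediction_grid = prediction_grid,
              verbosity = num(verbosity))
  structure(cfg, class = "run_config")
}

as_mcmc_config <- function(cfg) {
  mcmc_config(n_chains = cfg$n_chains, n_iterations = cfg$n_iterations,
              burn_in = cfg$burn_in, thin = cfg$thin, seed = cfg$seed,
              proposal_scale = cfg$proposal_scale, adapt = cfg$adapt,
              save_latent = cfg$save_latent)
}

as_prior_spec <- function(cfg) {
  prior_spec(fixed_sd = cfg$prior_fixed_sd, sd_upper = cfg$prior_sd_upper)
}

as_simulation_design <- function(cfg) {
  simulation_design(n_sites = cfg$n_sites, n_sierra = cfg$n_sierra,
                    n_years = cfg$n_years, n_occasions = cfg$n_occasions,
                    habitat1km_correlation = cfg$habitat1km_correlation,
                    first_year_start = cfg$first_year_start,
                    missing_prob = cfg$missing_prob)
}

# provenance header written at the top of every pipeline log
provenance_lines <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(unclass(cfg), file = tmp)
  hash <- unname(tools::md5sum(tmp))
  c(sprintf("# msoccu %s", as.character(utils::packageVersion("msoccu"))),
    sprintf("# config md5: %s", hash),
    sprintf("# seed: %d", as.integer(cfg$seed)),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
}

log_to <- function(cfg, name, lines) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cfg$out_dir, name)
  writeLines(lines, path)
  if (cfg$verbosity > 0) message(paste(lines, collapse = "\n"))
  invisible(path)
}
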