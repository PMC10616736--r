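#' Posterior predictions of occupancy and conditional reproduction
#'
#' Evaluates, for each retained draw, the occupancy probability `psi` and
#' the conditional reproduction (cub-occupancy) probability `R` at
#' requested covariate values, and summarizes the posterior mean and
#' central 95% credible interval.  Habitat is supplied as a *raw*
#' proportion and standardized internally with the constants stored at
#' fitting time.  Random-effect policies: `"typical"` evaluates the median
#' site (random effect 0); `"marginal"` averages the probability over the
#' random-effect distribution `Normal(0, sd^2)` within each draw by Monte
#' Carlo.
#'
#' @param draws a `posterior_draws` object from [run_mcmc()].
#' @param habitat5km raw habitat proportion(s) in `[0, 1]`.
#' @param ecoregion `"GreatBasin"` or `"SierraNevada"` (recycled).
#' @param policy `"typical"` or `"marginal"`.
#' @param n_marginal Monte-Carlo points per draw for the marginal policy.
#' @return A data.frame with one row per requested point: `habitat5km`,
#'   `ecoregion`, `psi_mean`, `psi_lower`, `psi_upper`, `R_mean`,
#'   `R_lower`, `R_upper`.
#' @export
predict_psi_R <- function(draws, habitat5km, ecoregion = "GreatBasin",
                          policy = c("typical", "marginal"),
                          n_marginal = 100) {
  stopifnot(inherits(draws, "posterior_draws"))
  policy <- match.arg(policy)
  if (any(habitat5km < 0 | habitat5km > 1))
    stop("habitat5km must be a raw proportion in [0, 1]", call. = FALSE)
  lv <- c("GreatBasin", "SierraNevada")
  ecoregion <- as.character(ecoregion)
  if (!all(ecoregion %in% lv))
    stop("ecoregion must be GreatBasin or SierraNevada", call. = FALSE)
  n_pts <- max(length(habitat5km), length(ecoregion))
  habitat5km <- rep_len(habitat5km, n_pts)
  ecoregion <- rep_len(ecoregion, n_pts)

  sc <- draws$standardization$habitat5km
  z5 <- (habitat5km - sc[["mean"]]) / sc[["sd"]]
  eco <- as.numeric(ecoregion == "SierraNevada")
  m <- as.matrix(draws)

  summ1 <- function(lp, sd_re) {
    if (policy == "typical") {
      pr <- inv_logit(lp)
    } else {
      pr <- vapply(seq_along(lp), function(d) {
        mean(inv_logit(lp[d] + stats::rnorm(n_marginal, 0, sd_re[d])))
      }, numeric(1))
    }
    c(mean(pr), stats::quantile(pr, c(0.025, 0.975), names = FALSE))
  }

  out <- lapply(seq_len(n_pts), function(g) {
    lp_psi <- m[, "occ_intercept"] + m[, "occ_beta_habitat"] * z5[g] +
      m[, "occ_beta_ecoregion"] * eco[g]
    lp_r <- m[, "rep_intercept"] + m[, "rep_beta_habitat"] * z5[g] +
      m[, "rep_beta_ecoregion"] * eco[g]
    s_psi <- summ1(lp_psi, m[, "sd_occ"])
    s_r <- summ1(lp_r, m[, "sd_rep"])
    data.frame(habitat5km = habitat5km[g], ecoregion = ecoregion[g],
               psi_mean = s_psi[1], psi_lower = s_psi[2],
               psi_upper = s_psi[3],
               R_mean = s_r[1], R_lower = s_r[2], R_upper = s_r[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Posterior distribution of finite-sample occupancy-state counts
#'
#' Tallies, per retained draw, the number of sites whose latent state in
#' the given year is unoccupied, adults-only, or with-cubs, plus the total
#' occupied (adults-only + with-cubs), and summarizes the posterior mean
#' and 95% credible interval of each count.
#'
#' @param draws a `posterior_draws` fitted with `save_latent = TRUE`.
#' @param year a year label present in the fitted data.
#' @return data.frame with rows `unoccupied`, `adults_only`, `with_cubs`,
#'   `total_occupied` and columns `state`, `mean`, `lower`, `upper`.
#' @export
expected_state_counts <- function(draws, year) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(draws$latent_state_draws))
    stop("latent states were not retained; refit with save_latent = TRUE",
         call. = FALSE)
  j <- match(as.character(year), draws$year_labels)
  if (is.na(j))
    stop("unknown year label: ", year, "; available: ",
         paste(draws$year_labels, collapse = ", "), call. = FALSE)
  sel <- which(draws$sy_year == j)
  d <- dim(draws$latent_state_draws)
  z <- matrix(aperm(draws$latent_state_draws[, , sel, drop = FALSE],
                    c(2, 1, 3)),
              d[1] * d[2], length(sel))
  n0 <- rowSums(z == 0L); n1 <- rowSums(z == 1L); n2 <- rowSums(z == 2L)
  tab <- rbind(unoccupied = n0, adults_only = n1, with_cubs = n2,
               total_occupied = n1 + n2)
  out <- data.frame(
    state = rownames(tab),
    mean = apply(tab, 1, mean),
    lower = apply(tab, 1, stats::quantile, probs = 0.025, names = FALSE),
    upper = apply(tab, 1, stats::quantile, probs = 0.975, names = FALSE),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Predictions over a covariate grid
#'
#' Vectorized [predict_psi_R()] over the cells of a grid of
#' `(habitat5km, ecoregion)` values, e.g. for mapping predicted occupancy
#' and conditional reproduction across a landscape.
#'
#' @param draws a `posterior_draws` object.
#' @param grid data.frame with columns `habitat5km` and `ecoregion`.
#' @param ... passed to [predict_psi_R()] (policy, etc.).
#' @return the grid with a `cell` id column and the prediction columns of
#'   [predict_psi_R()] appended.
#' @export
predict_grid <- function(draws, grid, ...) {
  stopifnot(is.data.frame(grid),
            all(c("habitat5km", "ecoregion") %in% names(grid)))
  out <- predict_psi_R(draws, grid$habitat5km, grid$ecoregion, ...)
  cbind(cell = seq_len(nrow(grid)), out)
}
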