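#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-variance form: with `m` chains of `n` draws, `W` the mean
#' within-chain variance and `B/n` the variance of the chain means, the
#' pooled variance estimate is `(n-1)/n * W + B/n` and
#' `Rhat = sqrt(((n-1)/n * W + B/n) / W)`.  Values below 1.1 are
#' conventionally taken as converged.  A split-chain variant (each chain
#' halved before the computation) is available via `split = TRUE`.
#'
#' @param draws a `posterior_draws` object, or a numeric matrix with one
#'   column per chain.
#' @param parameter parameter name (required for `posterior_draws` input).
#' @param split use split-chain Rhat (default `FALSE`, the classic form).
#' @return the Rhat statistic (scalar); `NA` if the draws are constant.
#' @export
gelman_rubin <- function(draws, parameter = NULL, split = FALSE) {
  if (inherits(draws, "posterior_draws")) {
    if (is.null(parameter))
      stop("supply a parameter name", call. = FALSE)
    k <- match(parameter, draws$parameter_names)
    if (is.na(k)) stop("unknown parameter: ", parameter, call. = FALSE)
    x <- t(draws$draws[, , k, drop = TRUE])
    if (is.null(dim(x))) x <- matrix(x, ncol = dim(draws$draws)[1])
  } else {
    x <- as.matrix(draws)
  }
  if (ncol(x) < 2L)
    stop("Gelman-Rubin diagnostic requires at least 2 chains", call. = FALSE)
  if (nrow(x) < 2L)
    stop("need at least 2 retained draws per chain", call. = FALSE)
  if (split) {
    h <- nrow(x) %/% 2L
    x <- cbind(x[seq_len(h), , drop = FALSE],
               x[h + seq_len(h), , drop = FALSE])
  }
  n <- nrow(x)
  w <- mean(apply(x, 2, stats::var))
  b_over_n <- stats::var(colMeans(x))
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}

#' Posterior summary table
#'
#' Mean, standard deviation, central 95% credible interval (2.5/50/97.5
#' percentiles) pooled over chains, plus the Gelman-Rubin Rhat per
#' parameter and a convergence flag (`Rhat < 1.1`).
#'
#' @param draws a `posterior_draws` object.
#' @param parameters optional subset of parameter names (default: all).
#' @param split passed to [gelman_rubin()].
#' @return A data.frame with one row per parameter.
#' @export
summarize_posterior <- function(draws, parameters = NULL, split = FALSE) {
  stopifnot(inherits(draws, "posterior_draws"))
  pooled <- as.matrix(draws)
  if (is.null(parameters)) parameters <- draws$parameter_names
  miss <- setdiff(parameters, draws$parameter_names)
  if (length(miss))
    stop("unknown parameter(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_chains <- dim(draws$draws)[1]
  rows <- lapply(parameters, function(pn) {
    v <- pooled[, pn]
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    rh <- if (n_chains >= 2)
      gelman_rubin(draws, pn, split = split) else NA_real_
    data.frame(parameter = pn, mean = mean(v), sd = stats::sd(v),
               q2.5 = q[1], median = q[2], q97.5 = q[3], rhat = rh,
               converged = if (is.na(rh)) NA else rh < 1.1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
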