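#' Site covariates for the multistate occupancy model
#'
#' Stores, per site, the proportion of suitable habitat within a coarse
#' (5 km) and a fine (1 km) buffer and a two-level ecoregion factor.
#' The coarse proportion enters the occupancy and reproduction submodels,
#' the fine proportion the detection submodels.  `GreatBasin` is always the
#' reference (intercept) level of `ecoregion`; the indicator is 1 for
#' `SierraNevada`.
#'
#' @param site character vector of site ids.
#' @param habitat5km,habitat1km habitat proportions in `[0, 1]` per site.
#' @param ecoregion character/factor with levels `GreatBasin`, `SierraNevada`.
#' @return An object of class `site_covariates`.  Standardized columns are
#'   added by [standardize_covariates()].
#' @export
site_covariates <- function(site, habitat5km, habitat1km, ecoregion) {
  site <- as.character(site)
  n <- length(site)
  if (anyDuplicated(site)) stop("duplicate site ids", call. = FALSE)
  if (length(habitat5km) != n || length(habitat1km) != n ||
      length(ecoregion) != n)
    stop("all covariate vectors must have one entry per site", call. = FALSE)
  for (nm in c("habitat5km", "habitat1km")) {
    v <- get(nm)
    if (anyNA(v) || !is.numeric(v) || any(v < 0 | v > 1)) {
      bad <- which(is.na(v) | v < 0 | v > 1)[1]
      stop(nm, " must be a proportion in [0, 1]; offending site: ",
           site[bad], " (value ", v[bad], ")", call. = FALSE)
    }
  }
  lv <- c("GreatBasin", "SierraNevada")
  eco <- as.character(ecoregion)
  if (!all(eco %in% lv))
    stop("ecoregion must be one of: ", paste(lv, collapse = ", "),
         "; found: ", paste(setdiff(unique(eco), lv), collapse = ", "),
         call. = FALSE)
  structure(
    list(site = site,
         habitat5km = as.numeric(habitat5km),
         habitat1km = as.numeric(habitat1km),
         ecoregion = factor(eco, levels = lv),
         standardized = FALSE),
    class = "site_covariates")
}

#' @export
print.site_covariates <- function(x, ...) {
  cat(sprintf("Site covariates: %d sites (%d SierraNevada, %d GreatBasin)%s\n",
              length(x$site), sum(x$ecoregion == "SierraNevada"),
              sum(x$ecoregion == "GreatBasin"),
              if (isTRUE(x$standardized)) ", standardized" else ""))
  invisible(x)
}

#' Read site covariates from CSV
#'
#' Expects columns `site, habitat5km, habitat1km, ecoregion`.  If a
#' [detection_history()] is supplied, covariates are checked against and
#' reordered to its site order.
#'
#' @param path path to a CSV file.
#' @param history optional [detection_history()] to align to.
#' @return A [site_covariates()] object (not yet standardized).
#' @export
read_covariates <- function(path, history = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "habitat5km", "habitat1km", "ecoregion")
  if (!all(need %in% names(df)))
    stop("covariate file requires columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  cov <- site_covariates(df$site, df$habitat5km, df$habitat1km, df$ecoregion)
  if (!is.null(history)) {
    stopifnot(inherits(history, "detection_history"))
    missing_cov <- setdiff(history$site_ids, cov$site)
    extra_cov <- setdiff(cov$site, history$site_ids)
    if (length(missing_cov) || length(extra_cov))
      stop("site mismatch between detections and covariates; ",
           "missing from covariates: ",
           paste(missing_cov, collapse = ", "),
           "; not in detections: ",
           paste(extra_cov, collapse = ", "), call. = FALSE)
    ord <- match(history$site_ids, cov$site)
    cov$site <- cov$site[ord]
    cov$habitat5km <- cov$habitat5km[ord]
    cov$habitat1km <- cov$habitat1km[ord]
    cov$ecoregion <- cov$ecoregion[ord]
  }
  cov
}

#' Write site covariates to CSV
#' @param x a [site_covariates()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(x, path) {
  stopifnot(inherits(x, "site_covariates"))
  utils::write.csv(
    data.frame(site = x$site, habitat5km = x$habitat5km,
               habitat1km = x$habitat1km,
               ecoregion = as.character(x$ecoregion)),
    path, row.names = FALSE)
  invisible(path)
}

#' Center and scale a covariate
#'
#' Standardizes to sample mean zero and sample standard deviation one
#' (denominator `n - 1`), returning the constants needed to place new
#' (e.g., prediction) inputs on the fitted scale.
#'
#' @param x numeric vector, length >= 2, with nonzero standard deviation.
#' @return A list with elements `z` (standardized values), `mean`, `sd`.
#' @examples
#' standardize(c(0, 1))$z  # -0.707..., +0.707...
#' @export
standardize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("covariate has zero variance and cannot be standardized",
         call. = FALSE)
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Standardize the habitat covariates of a site-covariate set
#'
#' Computes standardization constants over the analysis sites and stores
#' both the standardized columns and the constants, so later prediction
#' inputs can be transformed with the same constants.
#'
#' @param cov a [site_covariates()].
#' @return `cov` with `habitat5km_std`, `habitat1km_std` and
#'   `standardization` (per-covariate mean and sd) added, and
#'   `standardized = TRUE`.
#' @export
standardize_covariates <- function(cov) {
  stopifnot(inherits(cov, "site_covariates"))
  s5 <- standardize(cov$habitat5km)
  s1 <- standardize(cov$habitat1km)
  cov$habitat5km_std <- s5$z
  cov$habitat1km_std <- s1$z
  cov$standardization <- list(
    habitat5km = c(mean = s5$mean, sd = s5$sd),
    habitat1km = c(mean = s1$mean, sd = s1$sd))
  cov$standardized <- TRUE
  cov
}

# 0/1 indicator with GreatBasin as reference level
ecoregion_indicator <- function(cov) {
  as.numeric(cov$ecoregion == "SierraNevada")
}
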