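#' Detection-history container
#'
#' A `detection_history` stores observed occupancy states from repeated
#' surveys as a 3-dimensional integer array indexed by site, year (primary
#' season) and occasion (secondary period).  Observed states are coded
#' 0 = no detection, 1 = adults only, 2 = young (cubs) detected; `NA` marks
#' occasions with no active survey effort (e.g., camera not yet deployed).
#' Missing occasions are genuinely missing: they are skipped in the
#' likelihood, never treated as non-detections.
#'
#' @param y integer array of dimension `c(n_sites, n_years, n_occasions)`
#'   with values in `{0, 1, 2}` or `NA` for missing occasions.
#' @param site_ids character vector of site labels (default `s1..sN`).
#' @param year_labels character vector of year/season labels.
#' @return An object of class `detection_history` with elements `y`,
#'   `site_ids`, `year_labels`, `n_sites`, `n_years`, `n_occasions`.
#' @examples
#' y <- array(NA_integer_, c(2, 1, 3))
#' y[1, 1, ] <- c(0L, 1L, 2L)
#' dh <- detection_history(y, site_ids = c("s1", "s2"), year_labels = "2018")
#' dh$n_occasions
#' @export
detection_history <- function(y, site_ids = NULL, year_labels = NULL) {
  if (!is.array(y) || length(dim(y)) != 3L)
    stop("`y` must be a 3-d array (site x year x occasion)", call. = FALSE)
  storage.mode(y) <- "integer"
  vals <- y[!is.na(y)]
  if (length(vals) && !all(vals %in% 0:2)) {
    bad <- sort(unique(vals[!vals %in% 0:2]))
    stop("observed states must be 0, 1 or 2; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- dim(y)
  if (any(d < 1L)) stop("all dimensions must be positive", call. = FALSE)
  if (is.null(site_ids)) site_ids <- paste0("s", seq_len(d[1]))
  if (is.null(year_labels)) year_labels <- paste0("y", seq_len(d[2]))
  if (length(site_ids) != d[1])
    stop("length(site_ids) must equal dim(y)[1]", call. = FALSE)
  if (length(year_labels) != d[2])
    stop("length(year_labels) must equal dim(y)[2]", call. = FALSE)
  if (anyDuplicated(site_ids)) stop("duplicate site ids", call. = FALSE)
  if (anyDuplicated(year_labels)) stop("duplicate year labels", call. = FALSE)
  dimnames(y) <- list(as.character(site_ids), as.character(year_labels), NULL)
  structure(
    list(y = y,
         site_ids = as.character(site_ids),
         year_labels = as.character(year_labels),
         n_sites = d[1], n_years = d[2], n_occasions = d[3]),
    class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  n_obs <- sum(!is.na(x$y))
  cat("Multistate detection history\n")
  cat(sprintf("  %d sites x %d years x %d occasions (%d active occasions)\n",
              x$n_sites, x$n_years, x$n_occasions, n_obs))
  tab <- table(factor(x$y[!is.na(x$y)], levels = 0:2))
  cat(sprintf("  observed states: 0=%d  1=%d  2=%d\n",
              tab[["0"]], tab[["1"]], tab[["2"]]))
  invisible(x)
}

#' Read detection histories from CSV
#'
#' Two dialects are supported.  The *long* dialect has one row per
#' site-year-occasion with columns `site, year, occasion, state`; occasions
#' absent from the file, and rows whose state is empty/`NA`, are recorded as
#' missing.  The *wide* dialect has one row per site-year with columns
#' `site, year, occ1, occ2, ...`.  A missing occasion is never silently
#' converted to state 0.
#'
#' @param path path to a CSV file.
#' @param dialect `"long"` or `"wide"`.
#' @param n_occasions for the long dialect, the number of occasions per year;
#'   defaults to the maximum occasion index present.
#' @return A [detection_history()].
#' @export
read_detections <- function(path, dialect = c("long", "wide"),
                            n_occasions = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if (dialect == "long") {
    need <- c("site", "year", "occasion", "state")
    if (!all(need %in% names(df)))
      stop("long dialect requires columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    bad <- which(!is.na(df$state) & !df$state %in% 0:2)
    if (length(bad))
      stop("unknown state code(s) at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " (states must be 0/1/2 or NA)", call. = FALSE)
    key <- paste(df$site, df$year, df$occasion, sep = "\r")
    if (anyDuplicated(key)) {
      d <- which(duplicated(key))[1]
      stop("duplicate (site, year, occasion) at row ", d, call. = FALSE)
    }
    sites <- unique(as.character(df$site))
    years <- sort(unique(as.character(df$year)))
    occ <- suppressWarnings(as.integer(df$occasion))
    if (anyNA(occ) || any(occ < 1L))
      stop("occasion indices must be positive integers", call. = FALSE)
    K <- if (is.null(n_occasions)) max(occ) else as.integer(n_occasions)
    y <- array(NA_integer_, c(length(sites), length(years), K))
    i <- match(as.character(df$site), sites)
    j <- match(as.character(df$year), years)
    y[cbind(i, j, occ)] <- as.integer(df$state)
    detection_history(y, site_ids = sites, year_labels = years)
  } else {
    need <- c("site", "year")
    if (!all(need %in% names(df)))
      stop("wide dialect requires columns site, year plus occasion columns",
           call. = FALSE)
    occ_cols <- setdiff(names(df), need)
    if (!length(occ_cols)) stop("no occasion columns found", call. = FALSE)
    key <- paste(df$site, df$year, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (site, year) rows in wide file", call. = FALSE)
    states <- as.matrix(df[occ_cols])
    storage.mode(states) <- "integer"
    bad <- which(!is.na(states) & !states %in% 0:2, arr.ind = TRUE)
    if (nrow(bad))
      stop("unknown state code at row ", bad[1, 1], ", column ",
           occ_cols[bad[1, 2]], call. = FALSE)
    sites <- unique(as.character(df$site))
    years <- sort(unique(as.character(df$year)))
    K <- length(occ_cols)
    y <- array(NA_integer_, c(length(sites), length(years), K))
    i <- match(as.character(df$site), sites)
    j <- match(as.character(df$year), years)
    for (k in seq_len(K)) y[cbind(i, j, k)] <- states[, k]
    detection_history(y, site_ids = sites, year_labels = years)
  }
}

#' Write detection histories to CSV
#'
#' Inverse of [read_detections()]; round-trips observed states and
#' missingness exactly in either dialect.
#'
#' @param x a [detection_history()].
#' @param path output file path.
#' @param dialect `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(x, path, dialect = c("long", "wide")) {
  stopifnot(inherits(x, "detection_history"))
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    grid <- expand.grid(occasion = seq_len(x$n_occasions),
                        year = x$year_labels, site = x$site_ids,
                        stringsAsFactors = FALSE)
    grid$state <- x$y[cbind(match(grid$site, x$site_ids),
                            match(grid$year, x$year_labels),
                            grid$occasion)]
    utils::write.csv(grid[c("site", "year", "occasion", "state")],
                     path, row.names = FALSE, na = "NA")
  } else {
    rows <- expand.grid(year = x$year_labels, site = x$site_ids,
                        stringsAsFactors = FALSE)
    mat <- matrix(NA_integer_, nrow(rows), x$n_occasions)
    for (k in seq_len(x$n_occasions))
      mat[, k] <- x$y[cbind(match(rows$site, x$site_ids),
                            match(rows$year, x$year_labels), k)]
    colnames(mat) <- paste0("occ", seq_len(x$n_occasions))
    utils::write.csv(cbind(rows[c("site", "year")], as.data.frame(mat)),
                     path, row.names = FALSE, na = "NA")
  }
  invisible(path)
}
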