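#' Resolve a percentile-based threshold temperature
#'
#' The threshold theta is the empirical `percentile` quantile of daily maximum
#' temperature over the basis window (all days of the study period by
#' default). Exceedance days are the days inside the analysis season whose
#' `tmax` is strictly above theta; ties at theta contribute zero heat excess
#' under the hockey-stick term, so the strict inequality is inconsequential
#' for the regression but fixes the day census.
#'
#' @param exposure Exposure data.frame.
#' @param percentile Percentile in (0, 100).
#' @param season Months (integers 1-12) forming the analysis window; default
#'   May-September.
#' @param basis_window Optional `Date` vector of length 2 restricting the
#'   days over which the quantile is taken; `NULL` uses the full series.
#' @param quantile_type Quantile definition passed to [stats::quantile()];
#'   type 7 (linear interpolation between order statistics) is the default,
#'   type 1 (inverted empirical CDF) is the common alternative.
#' @return Object of class `"heat_threshold"`: a list with `theta`,
#'   `percentile`, `n_exceedance_days`, `exceedance_dates`, `season`,
#'   `quantile_type`.
#' @export
#' @examples
#' dat <- simulate_study(synthetic_config(n_years = 2, seed = 3))
#' compute_threshold(dat$exposure, percentile = 90)
compute_threshold <- function(exposure, percentile = 90, season = 5:9,
                              basis_window = NULL, quantile_type = 7) {
  exposure <- validate_exposure(exposure)
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      percentile <= 0 || percentile >= 100) {
    stop("percentile must be a single value strictly between 0 and 100",
         call. = FALSE)
  }
  basis <- exposure
  if (!is.null(basis_window)) {
    basis <- basis[basis$date >= basis_window[1] & basis$date <= basis_window[2], ]
  }
  if (nrow(basis) == 0L) stop("empty basis window", call. = FALSE)
  theta <- unname(stats::quantile(basis$tmax, percentile / 100,
                                  type = quantile_type, names = FALSE))
  in_season <- month_of(exposure$date) %in% season
  exceed <- exposure$date[in_season & exposure$tmax > theta]
  structure(list(theta = theta, percentile = percentile,
                 n_exceedance_days = length(exceed),
                 exceedance_dates = exceed, season = season,
                 quantile_type = quantile_type),
            class = "heat_threshold")
}

month_of <- function(dates) as.POSIXlt(dates)$mon + 1L

#' @export
print.heat_threshold <- function(x, ...) {
  cat(sprintf("Threshold temperature: %.2f degC (%gth percentile of tmax)\n",
              x$theta, x$percentile))
  cat(sprintf("Exceedance days (months %s): %d\n",
              paste(x$season, collapse = ","), x$n_exceedance_days))
  invisible(x)
}

#' Census exceedance days over a grid of percentiles
#'
#' One row per percentile with the resolved threshold and the number of
#' season-window days strictly above it. Counts are non-increasing in the
#' percentile because the quantile operator is monotone.
#'
#' @inheritParams compute_threshold
#' @param percentiles Numeric vector of percentiles in (0, 100).
#' @return data.frame with columns `percentile`, `theta`, `n_days`.
#' @export
exceedance_census <- function(exposure, percentiles = c(75, 80, 85, 90, 95, 99),
                              season = 5:9, basis_window = NULL,
                              quantile_type = 7) {
  rows <- lapply(percentiles, function(p) {
    th <- compute_threshold(exposure, p, season, basis_window, quantile_type)
    data.frame(percentile = p, theta = th$theta, n_days = th$n_exceedance_days)
  })
  do.call(rbind, rows)
}
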