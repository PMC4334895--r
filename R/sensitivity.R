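#' Sensitivity sweep over lags, threshold percentiles and pollutant modes
#'
#' Re-runs the fit and the attribution for every cell of the grid
#' `causes x lags x percentiles x pollutant modes` and returns one long-format
#' row per cell. The threshold is recomputed per percentile from the same
#' basis window. Pollutant-adjusted cells restrict the fitting window to the
#' date range with complete PM10/O3 data; to isolate the effect of adjustment
#' from the effect of the shorter window, the unadjusted model is re-reported
#' on that same window as rows with `window == "pollutant"`. A cell whose fit
#' fails is recorded with `converged = FALSE` and `NA` estimates; the grid is
#' never aborted. The sweep is a pure function of its inputs — no randomness.
#'
#' @param exposure Exposure data.frame.
#' @param mortality Wide mortality data.frame.
#' @param causes Cause labels to fit (default: every mortality column).
#' @param lags Subset of `c("lag0", "lag1", "lag2", "ma02")`.
#' @param percentiles Threshold percentiles.
#' @param pollutant_modes Subset of `c("unadjusted", "adjusted")`.
#' @param all_cause All-cause column label for attribution denominators.
#' @inheritParams heat_model
#' @return data.frame, one row per grid cell (plus the matched
#'   pollutant-window unadjusted rows when `"adjusted"` is requested), with
#'   columns `cause`, `lag`, `percentile`, `pollutant_mode`, `window`,
#'   `theta`, `n_exceedance_days`, `beta`, `se_beta`, `dispersion`, `rr`,
#'   `ci_low`, `ci_high`, `n_days`, `converged`, `ad`, `pct_of_cause`,
#'   `pct_of_total`.
#' @export
#' @examples
#' dat <- simulate_study(synthetic_config(n_years = 3, seed = 9))
#' tab <- run_sensitivity(dat$exposure, dat$mortality, causes = "All cause",
#'                        percentiles = c(90, 95))
#' tab[, c("percentile", "theta", "rr", "ad")]
run_sensitivity <- function(exposure, mortality,
                            causes = setdiff(names(mortality), "date"),
                            lags = "lag0",
                            percentiles = c(90, 93, 95, 99),
                            pollutant_modes = "unadjusted",
                            all_cause = "All cause",
                            confounders = c("humidity", "pressure", "dow", "trend"),
                            trend_df_per_year = 1,
                            season = 5:9,
                            basis_window = NULL,
                            quantile_type = 7) {
  exposure <- validate_exposure(exposure)
  mortality <- validate_mortality(mortality)
  stopifnot(length(causes) > 0, length(lags) > 0, length(percentiles) > 0)
  pollutant_modes <- match.arg(pollutant_modes, c("unadjusted", "adjusted"),
                               several.ok = TRUE)

  cell <- function(cause, lag, pct, mode, window, expo) {
    na_row <- data.frame(cause = cause, lag = lag, percentile = pct,
                         pollutant_mode = mode, window = window,
                         theta = NA_real_, n_exceedance_days = NA_integer_,
                         beta = NA_real_, se_beta = NA_real_,
                         dispersion = NA_real_, rr = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         n_days = NA_integer_, converged = FALSE,
                         ad = NA_real_, pct_of_cause = NA_real_,
                         pct_of_total = NA_real_)
    tryCatch({
      thr <- compute_threshold(expo, pct, season, basis_window, quantile_type)
      fit <- heat_model(expo, mortality, cause, theta = thr$theta, lag = lag,
                        confounders = confounders,
                        pollutants = (mode == "adjusted"),
                        trend_df_per_year = trend_df_per_year,
                        season = season, quantile_type = quantile_type)
      att <- heat_attribution(fit, mortality, all_cause = all_cause)
      data.frame(cause = cause, lag = lag, percentile = pct,
                 pollutant_mode = mode, window = window,
                 theta = thr$theta, n_exceedance_days = thr$n_exceedance_days,
                 beta = fit$beta, se_beta = fit$se_beta,
                 dispersion = fit$dispersion, rr = fit$rr,
                 ci_low = fit$rr_ci_low, ci_high = fit$rr_ci_high,
                 n_days = fit$n_days, converged = fit$converged,
                 ad = att$attributable_deaths,
                 pct_of_cause = att$pct_of_cause,
                 pct_of_total = att$pct_of_total)
    }, error = function(e) na_row)
  }

  expo_poll <- NULL
  if ("adjusted" %in% pollutant_modes) {
    ok <- !is.na(exposure$pm10) & !is.na(exposure$o3)
    if (!any(ok)) stop("adjusted mode requested but no complete pollutant days",
                       call. = FALSE)
    rng <- range(exposure$date[ok])
    expo_poll <- exposure[exposure$date >= rng[1] & exposure$date <= rng[2], ]
  }

  rows <- list()
  for (cause in causes) for (lag in lags) for (pct in percentiles) {
    for (mode in pollutant_modes) {
      if (mode == "unadjusted") {
        rows[[length(rows) + 1L]] <-
          cell(cause, lag, pct, "unadjusted", "full", exposure)
      } else {
        rows[[length(rows) + 1L]] <-
          cell(cause, lag, pct, "adjusted", "pollutant", exposure)
        # matched comparison: unadjusted model on the pollutant-covered window
        rows[[length(rows) + 1L]] <-
          cell(cause, lag, pct, "unadjusted", "pollutant", expo_poll)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
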