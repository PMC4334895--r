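# Display rounding used throughout: half away from zero, the convention of
# printed epidemiological tables (base round() is half-to-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Day-level attributable fractions from a heat slope
#'
#' For each analysis-season day, the day-specific relative risk is
#' `RR_t = exp(beta * max(0, L(tmax)_t - theta))` and the attributable
#' fraction `AF_t = (RR_t - 1) / RR_t`. AF is zero at or below the threshold,
#' strictly increasing in the heat excess when `beta > 0`, negative on
#' exceedance days when `beta < 0` (a protective slope), and always below 1.
#'
#' @param beta Log-RR per degC above threshold.
#' @param exposure Exposure data.frame.
#' @param theta Threshold temperature, degC.
#' @param lag Lag transform, as in [build_design()]; must match the fit that
#'   produced `beta`. Days without full lag history are dropped.
#' @param season Analysis months.
#' @return data.frame with columns `date`, `excess`, `rr`, `af`.
#' @export
#' @examples
#' dat <- simulate_study(synthetic_config(n_years = 2, seed = 5))
#' af <- daily_af(log(2), dat$exposure, theta = 30)
#' range(af$af)
daily_af <- function(beta, exposure, theta, lag = "lag0", season = 5:9) {
  exposure <- validate_exposure(exposure)
  stopifnot(is.finite(theta), is.finite(beta))
  lt <- lag_tmax(exposure, lag)
  keep <- month_of(exposure$date) %in% season & !is.na(lt)
  excess <- pmax(0, lt[keep] - theta)
  rr <- exp(beta * excess)
  data.frame(date = exposure$date[keep], excess = excess, rr = rr,
             af = (rr - 1) / rr)
}

#' Attributable-death proportions
#'
#' The two proportion columns of a cause-specific attribution table:
#' attributable deaths as a percentage of the cause's own warm-season deaths
#' and of all warm-season deaths. Both the unrounded values and the 2-decimal
#' display values (rounded half away from zero) are returned.
#'
#' @param ad Attributable deaths (may be negative for protective slopes).
#' @param deaths_cause Warm-season deaths from the cause.
#' @param deaths_total Warm-season deaths from all causes.
#' @return List with `pct_of_cause`, `pct_of_total` and their `_display`
#'   2-decimal counterparts.
#' @export
#' @examples
#' ad_proportions(975, 65675, 271633)
ad_proportions <- function(ad, deaths_cause, deaths_total) {
  pc <- 100 * ad / deaths_cause
  pt <- 100 * ad / deaths_total
  list(pct_of_cause = pc, pct_of_total = pt,
       pct_of_cause_display = round_half_up(pc, 2),
       pct_of_total_display = round_half_up(pt, 2))
}

#' Attributable deaths from an AF series and observed counts
#'
#' `AD = sum_t AF_t * D_t` over the attribution days, with proportions taken
#' against the cause-specific and all-cause death totals over those same
#' days. Per-cause results are independent: a negative AD (protective slope)
#' is reported as-is and never netted against other causes.
#'
#' @param af AF data.frame from [daily_af()].
#' @param mortality Wide mortality data.frame covering the AF dates.
#' @param cause Cause column to attribute.
#' @param all_cause Label of the all-cause column used for the
#'   percent-of-total denominator (`NA` denominator if absent).
#' @return Object of class `"heat_attribution"`: `cause`, `af` (the input
#'   series joined with deaths), `attributable_deaths` (unrounded),
#'   `attributable_deaths_rounded`, `deaths_cause_season`,
#'   `deaths_all_season`, `pct_of_cause`, `pct_of_total` and display-rounded
#'   counterparts.
#' @export
attributable_deaths <- function(af, mortality, cause,
                                all_cause = "All cause") {
  mortality <- validate_mortality(mortality)
  if (!cause %in% names(mortality)) {
    stop("cause '", cause, "' not found in the mortality table", call. = FALSE)
  }
  idx <- match(af$date, mortality$date)
  if (anyNA(idx)) {
    stop("attribution dates not covered by the mortality table: ",
         paste(utils::head(format(af$date[is.na(idx)]), 5), collapse = ", "),
         call. = FALSE)
  }
  deaths <- mortality[[cause]][idx]
  ad <- sum(af$af * deaths)
  d_cause <- sum(deaths)
  d_all <- if (all_cause %in% names(mortality))
    sum(mortality[[all_cause]][idx]) else NA_integer_
  pr <- ad_proportions(ad, d_cause, d_all)
  structure(list(cause = cause,
                 af = cbind(af, deaths = deaths),
                 attributable_deaths = ad,
                 attributable_deaths_rounded = round(ad),
                 deaths_cause_season = d_cause,
                 deaths_all_season = d_all,
                 pct_of_cause = pr$pct_of_cause,
                 pct_of_total = pr$pct_of_total,
                 pct_of_cause_display = pr$pct_of_cause_display,
                 pct_of_total_display = pr$pct_of_total_display),
            class = "heat_attribution")
}

#' Attribute heat deaths from a fitted model
#'
#' Convenience wrapper: computes the day-level AF series from the fit's own
#' slope, threshold and lag, restricted to the exact day set the model was
#' fitted on (so dropped days never contribute), and accumulates attributable
#' deaths for the fitted cause.
#'
#' @param fit A `"heat_fit"`.
#' @param mortality Wide mortality data.frame (the one the model was fitted
#'   against).
#' @param all_cause Label of the all-cause column.
#' @param exposure Optional exposure data.frame; only needed if the fit's
#'   stored day set must be re-derived.
#' @return A `"heat_attribution"`.
#' @export
#' @examples
#' dat <- simulate_study(synthetic_config(n_years = 3, seed = 2))
#' fit <- heat_model(dat$exposure, dat$mortality, "All cause")
#' heat_attribution(fit, dat$mortality)
heat_attribution <- function(fit, mortality, all_cause = "All cause",
                             exposure = NULL) {
  stopifnot(inherits(fit, "heat_fit"))
  rr <- exp(fit$beta * fit$heat)
  af <- data.frame(date = fit$dates, excess = fit$heat, rr = rr,
                   af = (rr - 1) / rr)
  attributable_deaths(af, mortality, fit$cause, all_cause)
}

#' @export
print.heat_attribution <- function(x, ...) {
  cat("Heat-attributable deaths\n")
  cat("  cause:               ", x$cause, "\n")
  cat(sprintf("  attributable deaths:  %.1f (rounded %d)\n",
              x$attributable_deaths, x$attributable_deaths_rounded))
  cat(sprintf("  %% of cause deaths:    %.2f%% (of %d)\n",
              x$pct_of_cause_display, x$deaths_cause_season))
  if (!is.na(x$deaths_all_season)) {
    cat(sprintf("  %% of all deaths:      %.2f%% (of %d)\n",
                x$pct_of_total_display, x$deaths_all_season))
  }
  invisible(x)
}
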