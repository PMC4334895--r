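# Lag transforms of daily maximum temperature. Lags are applied to the
# exposure series *before* thresholding, within contiguous runs of calendar
# days: a day without full lag history (start of the series or after a gap)
# gets NA and is later dropped with a logged reason.
lag_tmax <- function(exposure, lag = c("lag0", "lag1", "lag2", "ma02")) {
  lag <- match.arg(lag)
  x <- exposure$tmax
  block <- cumsum(c(1L, as.integer(diff(exposure$date) != 1)))
  shift <- function(v, k) c(rep(NA_real_, k), v[seq_len(length(v) - k)])
  out <- numeric(length(x))
  for (b in unique(block)) {
    i <- which(block == b)
    xi <- x[i]
    out[i] <- switch(lag,
      lag0 = xi,
      lag1 = shift(xi, 1L),
      lag2 = shift(xi, 2L),
      ma02 = (xi + shift(xi, 1L) + shift(xi, 2L)) / 3)
  }
  out
}

#' Build the regression design for the heat model
#'
#' Assembles, for every analysis-season day, the hockey-stick heat term
#' `max(0, L(tmax) - theta)` (with `L` the chosen lag transform), linear
#' humidity and pressure, day-of-week indicators (Sunday reference), a
#' natural cubic spline in calendar time for the long-term trend
#' (`trend_df_per_year` df per study year), and optionally PM10 and ozone.
#' Rows with any required covariate missing (lag history, pollutants) are
#' dropped and reported in the `dropped` element.
#'
#' @param exposure Exposure data.frame.
#' @param theta Threshold temperature in degC (see [compute_threshold()]).
#' @param lag One of `"lag0"`, `"lag1"`, `"lag2"`, `"ma02"`.
#' @param confounders Character subset of
#'   `c("humidity", "pressure", "dow", "trend")`.
#' @param pollutants Add PM10 and O3 terms? Requires non-missing columns.
#' @param trend_df_per_year Spline degrees of freedom per study year (>= 1
#'   total df after rounding).
#' @param season Analysis months, default May-September.
#' @return List with `data` (date plus model columns), `formula`, `dropped`
#'   (data.frame of excluded dates with reasons) and `theta`.
#' @export
build_design <- function(exposure, theta,
                         lag = "lag0",
                         confounders = c("humidity", "pressure", "dow", "trend"),
                         pollutants = FALSE,
                         trend_df_per_year = 1,
                         season = 5:9) {
  exposure <- validate_exposure(exposure)
  confounders <- match.arg(confounders,
                           c("humidity", "pressure", "dow", "trend"),
                           several.ok = TRUE)
  if (trend_df_per_year < 0) stop("trend_df_per_year must be >= 0", call. = FALSE)
  if (pollutants && (all(is.na(exposure$pm10)) || all(is.na(exposure$o3)))) {
    stop("pollutant adjustment requested but pm10/o3 columns are empty",
         call. = FALSE)
  }
  lt <- lag_tmax(exposure, lag)
  df <- data.frame(date = exposure$date,
                   heat = pmax(0, lt - theta),
                   lag_na = is.na(lt))
  df$humidity <- exposure$humidity
  df$pressure <- exposure$pressure
  if (pollutants) { df$pm10 <- exposure$pm10; df$o3 <- exposure$o3 }
  df <- df[month_of(df$date) %in% season, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows in the analysis season", call. = FALSE)

  dropped <- data.frame(date = as.Date(character()), reason = character())
  if (any(df$lag_na)) {
    dropped <- rbind(dropped, data.frame(date = df$date[df$lag_na],
                                         reason = "incomplete lag history"))
  }
  if (pollutants) {
    pna <- !df$lag_na & (is.na(df$pm10) | is.na(df$o3))
    if (any(pna)) {
      dropped <- rbind(dropped, data.frame(date = df$date[pna],
                                           reason = "missing pollutant data"))
    }
  }
  keep <- !df$date %in% dropped$date
  df <- df[keep, , drop = FALSE]
  df$heat[is.na(df$heat)] <- 0  # unreachable after drop; keeps NA checks simple
  df$lag_na <- NULL

  terms <- "heat"
  if ("humidity" %in% confounders) terms <- c(terms, "humidity") else df$humidity <- NULL
  if ("pressure" %in% confounders) terms <- c(terms, "pressure") else df$pressure <- NULL
  if ("dow" %in% confounders) {
    df$dow <- factor(weekdays(df$date, abbreviate = TRUE),
                     levels = c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat"))
    terms <- c(terms, "dow")
  }
  if ("trend" %in% confounders && trend_df_per_year > 0) {
    n_years <- length(unique(as.integer(format(df$date, "%Y"))))
    tdf <- max(1L, as.integer(round(trend_df_per_year * n_years)))
    df$trend <- splines::ns(as.numeric(df$date), df = tdf)
    terms <- c(terms, "trend")
  }
  if (pollutants) terms <- c(terms, "pm10", "o3")
  list(data = df,
       formula = stats::as.formula(paste("count ~", paste(terms, collapse = " + "))),
       dropped = dropped, theta = theta, lag = lag, season = season)
}

#' Fit the overdispersed Poisson heat regression
#'
#' Fits the log-linear count model by iteratively reweighted least squares
#' (Poisson likelihood, log link) and scales standard errors by the Pearson
#' dispersion `phi = chi^2 / (n - p)` — the quasi-Poisson estimator. Point
#' estimates are identical to a plain Poisson fit; only the covariance is
#' rescaled. The 95\% Wald interval on the relative risk per 1 degC is
#' `exp(beta +/- 1.959964 * se)`.
#'
#' @param design Output of [build_design()].
#' @param counts Non-negative integer vector aligned to `design$data` rows.
#' @param cause Optional cause label carried into the result.
#' @return Object of class `"heat_fit"`; see [heat_model()] for fields.
#' @export
fit_quasipoisson <- function(design, counts, cause = NA_character_) {
  dat <- design$data
  if (length(counts) != nrow(dat)) {
    stop("counts are not aligned to the design rows", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dat$count <- counts
  X <- stats::model.matrix(design$formula, dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::glm(design$formula, data = dat,
                    family = stats::quasipoisson(link = "log"),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    warning("IRLS did not converge within 100 iterations", call. = FALSE)
  }
  sm <- summary(fit)
  # a design without a heat term (e.g. an intercept-only reference fit) is
  # legal; the RR fields are then NA
  has_heat <- "heat" %in% rownames(sm$coefficients)
  beta <- if (has_heat) unname(stats::coef(fit)["heat"]) else NA_real_
  se <- if (has_heat) unname(sm$coefficients["heat", "Std. Error"]) else NA_real_
  z <- 1.959964
  out <- list(call = match.call(), cause = cause,
              beta = beta, se_beta = se,
              dispersion = unname(sm$dispersion),
              rr = exp(beta),
              rr_ci_low = exp(beta - z * se),
              rr_ci_high = exp(beta + z * se),
              n_days = nrow(dat),
              converged = fit$converged,
              theta = design$theta, lag = design$lag, season = design$season,
              dates = dat$date, heat = dat$heat, counts = counts,
              dropped = design$dropped, glm = fit)
  class(out) <- "heat_fit"
  out
}

#' Fit the heat-mortality model for one cause
#'
#' One-call interface: resolves the percentile threshold from the exposure
#' series, builds the lagged hockey-stick design over the analysis season,
#' aligns the daily death counts for `cause`, and fits the quasi-Poisson
#' regression. With `pollutants = TRUE` the fit (but not the threshold) is
#' restricted to the date range with complete PM10/O3 data.
#'
#' @param exposure Exposure data.frame (see [read_exposure()] or
#'   [simulate_weather()]).
#' @param mortality Wide mortality data.frame.
#' @param cause Column of `mortality` to model.
#' @param percentile Threshold percentile of tmax; ignored when `theta` is
#'   given directly.
#' @param theta Optional fixed threshold in degC.
#' @inheritParams build_design
#' @inheritParams compute_threshold
#' @return Object of class `"heat_fit"` with fields `cause`, `beta` (log-RR
#'   per degC above threshold), `se_beta` (dispersion-scaled), `dispersion`
#'   (Pearson phi-hat), `rr`, `rr_ci_low`, `rr_ci_high` (Wald 95\%),
#'   `n_days`, `converged`, `theta`, plus the underlying `glm` object for the
#'   standard accessor methods.
#' @seealso [relative_risk()], [heat_attribution()], [run_sensitivity()]
#' @export
#' @examples
#' dat <- simulate_study(synthetic_config(n_years = 3, seed = 11))
#' fit <- heat_model(dat$exposure, dat$mortality, cause = "All cause")
#' fit
#' relative_risk(fit)
heat_model <- function(exposure, mortality, cause = "All cause",
                       percentile = 90, theta = NULL,
                       lag = "lag0",
                       confounders = c("humidity", "pressure", "dow", "trend"),
                       pollutants = FALSE,
                       trend_df_per_year = 1,
                       season = 5:9,
                       basis_window = NULL,
                       quantile_type = 7) {
  exposure <- validate_exposure(exposure)
  mortality <- validate_mortality(mortality)
  if (!cause %in% names(mortality)) {
    stop("cause '", cause, "' not found in the mortality table", call. = FALSE)
  }
  thr <- NULL
  if (is.null(theta)) {
    thr <- compute_threshold(exposure, percentile, season, basis_window,
                             quantile_type)
    theta <- thr$theta
  }
  if (pollutants) {
    ok <- !is.na(exposure$pm10) & !is.na(exposure$o3)
    if (!any(ok)) stop("no days with complete pollutant data", call. = FALSE)
    rng <- range(exposure$date[ok])
    exposure <- exposure[exposure$date >= rng[1] & exposure$date <= rng[2], ]
  }
  design <- build_design(exposure, theta, lag, confounders, pollutants,
                         trend_df_per_year, season)
  idx <- match(design$data$date, mortality$date)
  if (anyNA(idx)) {
    stop("mortality table does not cover analysis dates: ",
         paste(utils::head(format(design$data$date[is.na(idx)]), 5),
               collapse = ", "), call. = FALSE)
  }
  fit <- fit_quasipoisson(design, mortality[[cause]][idx], cause = cause)
  fit$percentile <- if (is.null(thr)) NA_real_ else thr$percentile
  fit$threshold <- thr
  fit$pollutants <- pollutants
  fit$call <- match.call()
  fit
}

#' Relative risk for a temperature increment
#'
#' `exp(delta * beta)` with Wald 95\% limits obtained by transforming the
#' interval on `beta` identically.
#'
#' @param fit A `"heat_fit"`.
#' @param delta Temperature increment in degC (default 1).
#' @return Named numeric vector `c(rr, ci_low, ci_high)`.
#' @export
relative_risk <- function(fit, delta = 1) {
  stopifnot(inherits(fit, "heat_fit"))
  z <- 1.959964
  c(rr = exp(delta * fit$beta),
    ci_low = exp(delta * fit$beta - abs(delta) * z * fit$se_beta),
    ci_high = exp(delta * fit$beta + abs(delta) * z * fit$se_beta))
}

#' @export
print.heat_fit <- function(x, digits = 3, ...) {
  cat("Quasi-Poisson heat-mortality model\n")
  if (!is.na(x$cause)) cat("  cause:      ", x$cause, "\n")
  cat(sprintf("  threshold:   %.2f degC%s, lag: %s\n", x$theta,
              if (!is.null(x$percentile) && !is.na(x$percentile))
                sprintf(" (%gth pctile)", x$percentile) else "", x$lag))
  cat(sprintf("  RR per 1 degC above threshold: %.*f (95%% CI %.*f-%.*f)\n",
              digits, x$rr, digits, x$rr_ci_low, digits, x$rr_ci_high))
  cat(sprintf("  dispersion phi-hat: %.*f   days used: %d%s\n",
              digits, x$dispersion, x$n_days,
              if (x$converged) "" else "   [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.heat_fit <- function(object, ...) {
  structure(list(fit = object, glm_summary = summary(object$glm)),
            class = "summary.heat_fit")
}

#' @export
print.summary.heat_fit <- function(x, ...) {
  print(x$fit)
  if (nrow(x$fit$dropped)) {
    cat(sprintf("  dropped days: %d (%s)\n", nrow(x$fit$dropped),
                paste(unique(x$fit$dropped$reason), collapse = "; ")))
  }
  cat("\nCoefficients (quasi-Poisson, Pearson-dispersion SEs):\n")
  stats::printCoefmat(x$glm_summary$coefficients, signif.stars = FALSE)
  invisible(x)
}

#' @export
coef.heat_fit <- function(object, ...) stats::coef(object$glm)

#' @export
confint.heat_fit <- function(object, parm, level = 0.95, ...) {
  sm <- summary(object$glm)$coefficients
  if (missing(parm)) parm <- rownames(sm)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- sm[parm, "Estimate"]; se <- sm[parm, "Std. Error"]
  out <- cbind(est - z * se, est + z * se)
  dimnames(out) <- list(parm, sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100))
  out
}

#' @export
predict.heat_fit <- function(object, newdata, ...) {
  if (missing(newdata)) stats::predict(object$glm, ...)
  else stats::predict(object$glm, newdata = newdata, ...)
}

#' @export
residuals.heat_fit <- function(object, ...) stats::residuals(object$glm, ...)

#' @export
fitted.heat_fit <- function(object, ...) stats::fitted(object$glm)

#' Simulate death counts from a fitted heat model
#'
#' Parametric draws at the fitted means with the estimated Pearson
#' dispersion: negative binomial with variance `phi * mu` when `phi > 1`,
#' Poisson otherwise.
#'
#' @param object A `"heat_fit"`.
#' @param nsim Number of replicate series.
#' @param seed Optional seed.
#' @param ... Unused.
#' @export
simulate.heat_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object$glm)
  phi <- object$dispersion
  out <- as.data.frame(replicate(nsim, {
    if (phi > 1) stats::rnbinom(length(mu), size = mu / (phi - 1), mu = mu)
    else stats::rpois(length(mu), mu)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot the fitted exposure-response
#'
#' Daily deaths against lagged daily maximum temperature over the analysis
#' season, with the fitted hockey-stick mean curve (other covariates held at
#' their averages) and the threshold marked.
#'
#' @param x A `"heat_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.heat_fit <- function(x, ...) {
  tm <- x$theta + x$heat
  graphics::plot(tm, x$counts, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.5, 0.5),
                 xlab = sprintf("daily max temperature (%s), degC", x$lag),
                 ylab = sprintf("daily deaths (%s)",
                                if (is.na(x$cause)) "counts" else x$cause), ...)
  grid <- seq(min(tm), max(tm), length.out = 200)
  mu0 <- mean(x$counts) * exp(-x$beta * mean(x$heat))
  graphics::lines(grid, mu0 * exp(x$beta * pmax(0, grid - x$theta)), lwd = 2)
  graphics::abline(v = x$theta, lty = 2)
  invisible(x)
}
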