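test_that("hockey-stick heat term is zero below the threshold", {
  ex <- make_exposure(seq(20, 28, length.out = 40))
  d <- build_design(ex, theta = 30)
  expect_true(all(d$data$heat == 0))
  # and equals the excess above it
  d2 <- build_design(ex, theta = 24)
  expect_equal(d2$data$heat, pmax(0, ex$tmax - 24))
})

test_that("lag transforms shift exposure before thresholding and drop boundary days", {
  ex <- make_exposure(c(30, 31, 32, 33, 34, 35))
  d1 <- build_design(ex, theta = 30, lag = "lag1")
  expect_equal(nrow(d1$data), 5L)                 # first day lacks history
  expect_equal(d1$data$heat, pmax(0, c(30, 31, 32, 33, 34) - 30))
  expect_equal(d1$dropped$reason, "incomplete lag history")

  dm <- build_design(ex, theta = 30, lag = "ma02")
  expect_equal(nrow(dm$data), 4L)                 # first two days dropped
  ma <- (c(30, 31, 32, 33) + c(31, 32, 33, 34) + c(32, 33, 34, 35)) / 3
  expect_equal(dm$data$heat, pmax(0, ma - 30))

  # a calendar gap starts a new contiguous block with its own boundary
  gap <- rbind(ex[1:3, ], transform(ex[4:6, ], date = date + 5))
  dg <- build_design(gap, theta = 30, lag = "lag1")
  expect_equal(nrow(dg$data), 4L)
  expect_equal(nrow(dg$dropped), 2L)
})

test_that("day-of-week indicators are one-hot with Sunday reference", {
  dat <- simulate_study(small_config())
  d <- build_design(dat$exposure, theta = 30)
  X <- model.matrix(d$formula, transform(d$data, count = 0))
  dow_cols <- grep("^dow", colnames(X))
  expect_length(dow_cols, 6L)
  monday <- weekdays(d$data$date, abbreviate = TRUE) == "Mon"
  expect_true(all(rowSums(X[, dow_cols, drop = FALSE])[monday] == 1))
  expect_true(all(X[monday, "dowMon"] == 1))
  sunday <- weekdays(d$data$date, abbreviate = TRUE) == "Sun"
  expect_true(all(rowSums(X[sunday, dow_cols, drop = FALSE]) == 0))
})

test_that("intercept-only fit recovers the closed-form mean and dispersion", {
  set.seed(8)
  counts <- rpois(60, 12)
  design <- list(data = data.frame(date = as.Date("2000-05-01") + 0:59),
                 formula = count ~ 1,
                 dropped = data.frame(date = as.Date(character()),
                                      reason = character()),
                 theta = 0, lag = "lag0", season = 5:9)
  fit <- fit_quasipoisson(design, counts)
  expect_equal(unname(coef(fit)[1]), log(mean(counts)), tolerance = 1e-10)
  expect_equal(fit$dispersion,
               sum((counts - mean(counts))^2 / mean(counts)) / (60 - 1),
               tolerance = 1e-5)
})

test_that("IRLS matches direct likelihood maximization on a small fixture", {
  set.seed(21)
  n <- 20
  x1 <- rnorm(n); x2 <- runif(n)
  mu <- exp(1 + 0.4 * x1 - 0.6 * x2)
  y <- rpois(n, mu)
  design <- list(data = data.frame(date = as.Date("2000-06-01") + 0:(n - 1),
                                   x1 = x1, x2 = x2),
                 formula = count ~ x1 + x2,
                 dropped = data.frame(date = as.Date(character()),
                                      reason = character()),
                 theta = 0, lag = "lag0", season = 5:9)
  fit <- fit_quasipoisson(design, y)
  # brute-force oracle: generic optimizer on the Poisson log-likelihood
  X <- cbind(1, x1, x2)
  nll <- function(b) { eta <- X %*% b; sum(exp(eta)) - sum(y * eta) }
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-6)
})

test_that("quasi-Poisson rescales standard errors but never point estimates", {
  dat <- simulate_study(small_config())
  fit <- heat_model(dat$exposure, dat$mortality, "All cause")
  pois <- glm(fit$glm$formula, data = fit$glm$data, family = poisson())
  expect_equal(coef(fit), coef(pois), tolerance = 1e-10)
  se_pois <- summary(pois)$coefficients["heat", "Std. Error"]
  expect_equal(fit$se_beta, se_pois * sqrt(fit$dispersion), tolerance = 1e-6)
  expect_gt(fit$dispersion, 0)
  expect_true(fit$rr_ci_low <= fit$rr && fit$rr <= fit$rr_ci_high)
})

test_that("rank-deficient designs are rejected, naming the collinear columns", {
  dat <- simulate_study(small_config())
  # all days below theta: identically-zero heat column must not be dropped
  # silently
  expect_error(heat_model(dat$exposure, dat$mortality, "All cause",
                          theta = 99),
               "rank deficient.*heat")
})

test_that("pollutant adjustment restricts the window and demands the columns", {
  cfg <- synthetic_config(n_years = 12, start_year = 1995, seed = 12,
                          pollutant_params = list(start_year = 2001L,
                                                  pm10_meanlog = log(55),
                                                  pm10_sdlog = 0.45,
                                                  o3_mean = 33,
                                                  o3_amplitude = 14,
                                                  o3_sd = 8))
  dat <- simulate_study(cfg)
  fit_adj <- heat_model(dat$exposure, dat$mortality, "All cause",
                        pollutants = TRUE)
  expect_true(all(format(fit_adj$dates, "%Y") >= "2001"))
  expect_true(all(c("pm10", "o3") %in% names(coef(fit_adj))))
  nopoll <- dat$exposure
  nopoll$pm10 <- NA_real_; nopoll$o3 <- NA_real_
  expect_error(heat_model(nopoll, dat$mortality, "All cause",
                          pollutants = TRUE), "pollutant")
})

test_that("relative risk transforms the slope and interval coherently", {
  dat <- simulate_study(small_config())
  fit <- heat_model(dat$exposure, dat$mortality, "All cause")
  rr1 <- relative_risk(fit, 1)
  expect_equal(unname(rr1["rr"]), exp(fit$beta))
  expect_equal(unname(rr1["rr"]), fit$rr)
  rr2 <- relative_risk(fit, 2)
  expect_equal(unname(rr2["rr"]), unname(rr1["rr"])^2, tolerance = 1e-12)
  # beta = 0 gives RR 1 with a log-symmetric interval
  fit0 <- fit; fit0$beta <- 0; fit0$se_beta <- 0.01
  r <- relative_risk(fit0)
  expect_equal(unname(r["rr"]), 1)
  expect_equal(log(unname(r["ci_high"])), -log(unname(r["ci_low"])),
               tolerance = 1e-12)
})

test_that("accessor methods delegate to the underlying GLM", {
  dat <- simulate_study(small_config())
  fit <- heat_model(dat$exposure, dat$mortality, "All cause")
  expect_equal(length(fitted(fit)), fit$n_days)
  expect_equal(length(residuals(fit)), fit$n_days)
  expect_equal(unname(predict(fit)[1]), unname(predict(fit$glm)[1]))
  ci <- confint(fit, "heat")
  expect_lt(ci[1, 1], fit$beta)
  expect_gt(ci[1, 2], fit$beta)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(fit$n_days, 2L))
  expect_true(all(sims >= 0))
  expect_output(print(summary(fit)), "Coefficients")
})
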