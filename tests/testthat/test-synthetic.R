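test_that("the generator is deterministic in seed and config", {
  a <- simulate_study(small_config())
  b <- simulate_study(small_config())
  expect_identical(a$exposure, b$exposure)
  expect_identical(a$mortality, b$mortality)
  c <- simulate_study(synthetic_config(n_years = 2, start_year = 2000,
                                       seed = 43))
  expect_false(identical(a$exposure$tmax, c$exposure$tmax))
})

test_that("noise-free degenerate config gives a constant temperature", {
  cfg <- small_config(temp_daily_sd = 0, temp_seasonal_amplitude = 0,
                      temp_mean_annual = 26.5)
  w <- simulate_weather(cfg)
  expect_true(all(w$tmax == 26.5))
  expect_true(all(w$tmin <= w$tmean & w$tmean <= w$tmax))
  expect_true(all(w$humidity > 0 & w$humidity <= 100))
  expect_true(all(w$pressure > 0))
})

test_that("warm-season temperature mean matches the closed-form expectation", {
  cfg <- synthetic_config(n_years = 18, seed = 7)
  w <- simulate_weather(cfg)
  warm <- (as.POSIXlt(w$date)$mon + 1L) %in% 5:9
  # closed form: mean of the sinusoid over the actual warm-season dates
  doy <- as.integer(format(w$date[warm], "%j"))
  expected <- cfg$temp_mean_annual + cfg$temp_seasonal_amplitude *
    mean(cos(2 * pi * (doy - 213) / 365.25))
  se <- cfg$temp_daily_sd / sqrt(sum(warm))
  expect_lt(abs(mean(w$tmax[warm]) - expected), 3 * se)
})

test_that("invalid config fields are rejected by name", {
  expect_error(synthetic_config(n_years = 0), "n_years")
  expect_error(synthetic_config(dispersion = 0.5), "dispersion")
  expect_error(synthetic_config(cause_baselines = c(a = -1)), "cause_baselines")
  expect_error(synthetic_config(dow_effects = rep(1, 6)), "dow_effects")
})

test_that("a null model generates homogeneous Poisson counts", {
  cfg <- flat_config(n_years = 2, start_year = 2000, seed = 10,
                     true_log_rr_per_degC = 0,
                     cause_baselines = c(x = 100), dispersion = 1)
  dat <- simulate_study(cfg)
  n <- nrow(dat$mortality)
  expect_lt(abs(mean(dat$mortality$x) - 100), 3 * sqrt(100 / n))
})

test_that("the expected count doubles per degree when beta = log 2", {
  cfg <- flat_config(true_log_rr_per_degC = log(2), true_threshold = 30,
                     cause_baselines = c(x = 10))
  # two same-weekday days, one at the threshold, one 1 degC above
  ex <- make_exposure(c(30, 28, 28, 28, 28, 28, 28, 31))
  mu <- mortality_expectation(ex, cfg)
  expect_equal(unname(mu[8, "x"] / mu[1, "x"]), 2)
  expect_equal(unname(mu[1, "x"]), unname(mu[2, "x"]))  # at threshold: zero excess
})

test_that("simulated counts reproduce the configured mean-variance pair", {
  # constant climate so counts are iid NB with mean 50, variance 4 * 50
  cfg <- flat_config(n_years = 28, start_year = 1990, seed = 20,
                     temp_daily_sd = 0, temp_seasonal_amplitude = 0,
                     temp_mean_annual = 20, true_threshold = 30,
                     cause_baselines = c(x = 50), dispersion = 4)
  dat <- simulate_study(cfg)
  x <- dat$mortality$x
  n <- length(x)
  expect_gte(n, 10000)
  ratio <- var(x) / mean(x)
  # Monte-Carlo oracle for the sampling SE of the variance/mean ratio
  set.seed(1)
  oracle <- replicate(200, {
    z <- rnbinom(n, size = 50 / 3, mu = 50)
    var(z) / mean(z)
  })
  expect_lt(abs(ratio - 4), 3 * sd(oracle))
})

test_that("sub-threshold days are bit-identical across heat slopes", {
  cfg0 <- flat_config(n_years = 2, start_year = 2000, seed = 31,
                      true_log_rr_per_degC = 0)
  cfg1 <- flat_config(n_years = 2, start_year = 2000, seed = 31,
                      true_log_rr_per_degC = 0.15)
  w <- simulate_weather(cfg0)
  m0 <- simulate_mortality(w, cfg0)
  m1 <- simulate_mortality(w, cfg1)
  below <- w$tmax <= cfg0$true_threshold
  expect_gt(sum(!below), 0)                 # the comparison is non-vacuous
  for (cause in setdiff(names(m0), "date")) {
    expect_identical(m0[[cause]][below], m1[[cause]][below])
  }
  expect_false(identical(m0[["All cause"]][!below], m1[["All cause"]][!below]))
})

test_that("mortality generation demands contiguous exposure days", {
  dat <- simulate_study(small_config())
  gappy <- dat$exposure[-5, ]
  expect_error(mortality_expectation(gappy, small_config()), "contiguous")
})
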