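test_that("the tricube smoother is exact on collinear and constant data", {
  x <- 1:10
  y <- 2 * x + 1
  sm <- lowess_tricube(x, y, span = 1.0)
  expect_equal(sm$fitted, y, tolerance = 1e-12)

  yc <- rep(3.5, 10)
  expect_equal(lowess_tricube(x, yc, span = 1.0)$fitted, yc, tolerance = 1e-12)

  expect_error(lowess_tricube(1:2, 1:2), "at least 3")
})

test_that("the smoother agrees with a pointwise weighted-least-squares oracle", {
  set.seed(33)
  x <- runif(20, 0, 10)
  y <- sin(x) + rnorm(20, 0, 0.3)
  for (span in c(1.0, 0.7)) {
    sm <- lowess_tricube(x, y, span = span, eval_x = x)
    n <- length(x)
    q <- min(n, max(2L, as.integer(ceiling(span * n))))
    oracle <- vapply(x, function(x0) {
      d <- abs(x - x0)
      h <- sort(d)[q]
      w <- ifelse(d < h, (1 - (d / h)^3)^3, 0)
      fit <- lm(y ~ x, weights = w)
      unname(predict(fit, data.frame(x = x0)))
    }, numeric(1))
    expect_equal(sm$fitted[match(x, sm$x)], oracle, tolerance = 1e-8)
  }
})

test_that("the RR-AD scatter keeps only significant causes with positive AD", {
  results <- data.frame(
    cause = c("a", "b", "c", "d", "e"),
    rr = c(1.03, 1.05, 1.08, 1.01, 0.97),
    ci_low = c(1.02, 1.01, 1.03, 0.99, 0.95),
    ci_high = c(1.04, 1.09, 1.13, 1.03, 0.99),
    ad = c(3000, 500, 50, 40, -100))
  sc <- rr_ad_scatter(results)
  expect_setequal(sc$cause, c("a", "b", "c"))          # d: n.s., e: AD <= 0
  excluded <- attr(sc, "excluded")
  expect_setequal(excluded$cause, c("d", "e"))
  expect_match(excluded$reason[excluded$cause == "d"], "non-significant")
  expect_equal(sc$log10_ad, log10(c(3000, 500, 50)))
  expect_error(rr_ad_scatter(results[1:2, ]), "fewer than 3")
})

test_that("rare high-RR causes sit at the low-AD end of the scatter", {
  # inverse baseline-slope pairing: common causes get small slopes, rare
  # causes large ones; the negative RR-AD rank relationship then emerges
  cfg <- synthetic_config(
    n_years = 8, start_year = 2000, seed = 60,
    cause_baselines = c(common = 100, mid = 20, low = 4, rare = 1),
    true_log_rr_per_degC = c(common = 0.02, mid = 0.05, low = 0.09,
                             rare = 0.14))
  dat <- simulate_study(cfg)
  tab <- run_sensitivity(dat$exposure, dat$mortality,
                         causes = names(cfg$cause_baselines),
                         percentiles = 90, all_cause = "common")
  expect_true(all(tab$converged))
  expect_lt(cor(tab$rr, log10(tab$ad), method = "spearman"), 0)
})

test_that("make_report writes consistent tables and a digest-bearing manifest", {
  dat <- simulate_study(small_config())
  out <- withr::local_tempdir()
  inp <- withr::local_tempfile(fileext = ".csv")
  write_exposure(dat$exposure, inp)
  rep1 <- make_report(dat$exposure, dat$mortality, out,
                      causes = c("All cause", "All cardiovascular",
                                 "Respiratory system", "Diabetes mellitus"),
                      input_paths = inp)
  expect_true(all(file.exists(file.path(out, c("attribution.csv",
                                               "forest.csv",
                                               "manifest.json")))))
  tab <- read.csv(file.path(out, "attribution.csv"), check.names = FALSE)
  # every display number recomputes from the stored unrounded values
  expect_equal(tab$pct_of_cause_display,
               sign(tab$pct_of_cause) *
                 floor(abs(tab$pct_of_cause) * 100 + 0.5) / 100)
  expect_equal(tab$ad_rounded, round(tab$ad))
  # one row's pct columns equal hand arithmetic from the fit it came from
  fit <- heat_model(dat$exposure, dat$mortality, "All cardiovascular")
  att <- heat_attribution(fit, dat$mortality)
  row <- tab[tab$cause == "All cardiovascular", ]
  expect_equal(row$ad, att$attributable_deaths, tolerance = 1e-10)
  expect_equal(row$pct_of_cause,
               100 * att$attributable_deaths / att$deaths_cause_season,
               tolerance = 1e-10)
  expect_equal(row$pct_of_total,
               100 * att$attributable_deaths / att$deaths_all_season,
               tolerance = 1e-10)

  manifest1 <- readLines(file.path(out, "manifest.json"))
  expect_match(paste(manifest1, collapse = ""), "md5")

  # manifest digest changes iff an input byte changes
  rep2 <- make_report(dat$exposure, dat$mortality, out,
                      causes = "All cause", input_paths = inp)
  m_same <- rep2$manifest$inputs$md5
  cat("x", file = inp, append = TRUE)
  rep3 <- make_report(dat$exposure, dat$mortality, out,
                      causes = "All cause", input_paths = inp)
  expect_false(identical(rep3$manifest$inputs$md5, m_same))
})
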