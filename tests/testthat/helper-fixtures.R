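# Shared fixture builders. Everything is generated in code; no stored data.

# a hand-built exposure table with valid covariates and the given tmax values
make_exposure <- function(tmax, start = as.Date("2000-05-01")) {
  n <- length(tmax)
  data.frame(date = seq(start, by = "day", length.out = n),
             tmax = tmax, tmean = tmax - 2, tmin = tmax - 4,
             humidity = rep(60, n), pressure = rep(1010, n),
             pm10 = rep(NA_real_, n), o3 = rep(NA_real_, n))
}

# small synthetic study config: short, fast, deterministic
small_config <- function(...) {
  synthetic_config(n_years = 2, start_year = 2000, seed = 42, ...)
}

# a config with every nuisance effect switched off, for moment checks
flat_config <- function(...) {
  synthetic_config(dow_effects = rep(1, 7), trend_slope = 0,
                   confounder_effects = c(humidity = 0, pressure = 0),
                   pollutant_params = NULL, ...)
}
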