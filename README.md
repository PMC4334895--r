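# heatmort

Quantifying the mortality burden of high ambient temperature from daily
time series — for environmental epidemiologists working with city-level
death registers and weather-station data.

Hot days kill, but the diseases most *sensitive* to heat (highest relative
risk) are not the ones that contribute the most *attributable* deaths: the
burden is dominated by common conditions with modest risk increases.
Separating the two requires estimating, per cause of death, both a relative
risk and an attributable-death total. `heatmort` implements that analysis
for warm-season (May–September) daily series:

* **Threshold exposure–response.** Daily counts $Y_t$ follow an
  overdispersed (quasi-Poisson) log-linear model
  $\log E[Y_t] = \alpha + \beta\,\max(0, T_t - \theta) + \text{confounders}$,
  with $T_t$ the (optionally lagged) daily maximum temperature and $\theta$
  a percentile of its study-period distribution (90th by default).
  Confounders: humidity, air pressure, day of week, a natural-spline
  long-term trend, optionally PM10 and ozone. The headline estimate is
  $RR = e^\beta$, the relative risk per 1 °C above threshold, with
  dispersion-scaled Wald 95% limits.
* **Attributable-death accounting.** Day-specific attributable fractions
  $AF_t = (RR_t - 1)/RR_t$ with $RR_t = e^{\beta \max(0, T_t-\theta)}$,
  accumulated as $AD = \sum_t AF_t D_t$ against observed deaths, reported
  with AD as a share of the cause's own deaths and of all deaths.
* **Sensitivity sweeps** over lags (same-day, lag 1, lag 2, moving average
  0–2), threshold percentiles (90/93/95/99) and pollutant adjustment.
* **ICD-10 cause taxonomy** (main categories and overlapping
  sub-categories at code-stem resolution) and validated CSV readers for
  weather and mortality tables, including line-listed deaths.
* **A synthetic-data generator** with a known, recoverable threshold
  effect, emulating an 18-year East Asian metropolitan study design, used
  throughout the tests for parameter-recovery and direction checks.

## Worked example

```r
library(heatmort)

dat <- simulate_study(synthetic_config(seed = 42))   # 18 years of daily data

compute_threshold(dat$exposure, percentile = 90)
#> Threshold temperature: 30.10 degC (90th percentile of tmax)
#> Exceedance days (months 5,6,7,8,9): 655

fit <- heat_model(dat$exposure, dat$mortality, cause = "All cause")
fit
#> Quasi-Poisson heat-mortality model
#>   cause:       All cause
#>   threshold:   30.10 degC (90th pctile), lag: lag0
#>   RR per 1 degC above threshold: 1.029 (95% CI 1.025-1.033)
#>   dispersion phi-hat: 1.495   days used: 2754

heat_attribution(fit, dat$mortality)
#> Heat-attributable deaths
#>   cause:                All cause
#>   attributable deaths:  4184.8 (rounded 4185)
#>   % of cause deaths:    1.52% (of 275780)
#>   % of all deaths:      1.52% (of 275780)
```

The generator's true slope is 0.0296 (RR 1.030); the fit recovers 1.029
with the truth inside the interval, and the Pearson dispersion 1.495 sits
at the generative 1.5. Of the 275,780 warm-season deaths in this
simulation, 4,185 (1.52%) are attributable to the 655 days above the
30.1 °C threshold. Raising the threshold percentile raises the RR but
shrinks the exceedance-day count and the burden:

```r
run_sensitivity(dat$exposure, dat$mortality, causes = "All cause",
                percentiles = c(90, 93, 95, 99))
#>   percentile theta n_exceedance_days    rr     ad
#> 1         90 30.10               655 1.029 4184.8
#> 2         93 31.13               460 1.037 3196.5
#> 3         95 31.94               329 1.045 2412.6
#> 4         99 34.44                66 1.073  456.9
```

`make_report()` writes the per-cause attribution table, forest-plot data
and the RR-versus-log10(AD) scatter with its tricube LOWESS smooth as
plotting-ready CSVs plus a manifest with input digests.

See `vignette source in vignettes/heat-attributable-mortality.Rmd` for the
model, the generator's design and its limitations, and all numerical
conventions.

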