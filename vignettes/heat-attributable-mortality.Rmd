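---
title: "Methods: heat-attributable mortality from daily time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat-attributable mortality from daily time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmort)
```

## The model

City-level mortality rises above a threshold temperature, producing the
familiar J-shaped exposure-response. `heatmort` implements the
threshold ("hockey-stick") form of that relationship for warm-season daily
time series. For one cause of death, the daily count $Y_t$ is modelled as
overdispersed Poisson with log link:

$$
\log E[Y_t] = \alpha + \beta \, \max(0,\, T_t - \theta)
  + \gamma_1 \mathrm{humidity}_t + \gamma_2 \mathrm{pressure}_t
  + \mathrm{dow}_t + s(t),
$$

where $T_t$ is the (possibly lagged) daily maximum temperature, $\theta$ is
the threshold, $\mathrm{dow}_t$ are day-of-week indicators (Sunday
reference) and $s(t)$ is a natural cubic spline in calendar time capturing
long-term trends. Optionally PM10 and daily-maximum ozone enter linearly.
The variance is $\mathrm{Var}[Y_t] = \phi\, E[Y_t]$: coefficients are the
Poisson maximum-likelihood estimates (fitted by iteratively reweighted least
squares via `stats::glm`), and standard errors are scaled by the Pearson
dispersion $\hat\phi = \chi^2_{\mathrm{Pearson}} / (n - p)$. The quantity of
interest is the relative risk per 1 degC above threshold,
$RR = e^\beta$, with Wald 95% limits $e^{\beta \pm 1.959964\,se}$.

The threshold is not estimated from the regression. It is fixed in advance
as an empirical percentile (default the 90th) of the daily-maximum
temperature distribution over the study period, and the analysis is
restricted to the warm season (May-September). Grid-search or segmented
estimation of $\theta$ is deliberately out of scope; the percentile
convention keeps the exposure definition independent of the outcome series
and makes sensitivity analysis straightforward (`run_sensitivity()` refits
at the 90th, 93rd, 95th and 99th percentiles).

Given a fitted slope, the burden side of the analysis converts each day's
excess into a day-specific attributable fraction

$$
RR_t = e^{\beta \max(0, T_t - \theta)}, \qquad
AF_t = \frac{RR_t - 1}{RR_t},
$$

and accumulates attributable deaths $AD = \sum_t AF_t D_t$ over the
analysis days, where $D_t$ is the observed count. $AF_t$ is day-specific
rather than a constant per-cause fraction: the daily reading follows from
computing fractions at each day's own excess, and it is what makes $AD$
sensitive to how often and how far the threshold is exceeded. $AD$ is
reported unrounded and rounded, alongside two proportions: $AD$ over the
cause's own warm-season deaths and $AD$ over all warm-season deaths. A
negative slope (observed in practice for self-harm) yields negative $AF_t$
and $AD$; per-cause results are independent and never netted against each
other.

## Parameters that matter

* `percentile` (default 90) — threshold percentile of daily maximum
  temperature, taken over all days of the study period by default
  (`basis_window` restricts it). Empirical quantiles use the
  linear-interpolation convention (type 7), with type 1 available to match
  other software; the choice moves $\theta$ by at most the gap between
  adjacent order statistics.
* `lag` — `lag0` (same-day, default), `lag1`, `lag2`, or `ma02` (moving
  average of lags 0-2). Lags apply to temperature *before* thresholding:
  the exposure day is shifted, not the excess. Days without full lag
  history at the start of a contiguous block are dropped and logged.
* `trend_df_per_year` (default 1) — spline df per study year for $s(t)$.
  One df per year absorbs between-year drift while leaving short-term heat
  variation to the heat term; raising it trades confounding control against
  the risk of absorbing genuine heat effects.
* `confounders` — humidity and pressure enter linearly; there is no strong
  basis for smoothing them in warm-season-only data, and linear entry keeps
  the fit identifiable for rare causes.
* `pollutants` (default off) — adds PM10 and ozone and restricts the fit to
  the date range with complete pollutant data (monitoring often starts
  mid-study). `run_sensitivity()` pairs every adjusted fit with an
  unadjusted fit on the same restricted window so adjustment is not
  confounded with the window change.

## The synthetic-data generator

Real city mortality registers are rarely redistributable, so the package
ships a generator (`synthetic_config()`, `simulate_study()`) whose defaults
emulate an 18-year East Asian metropolitan design: daily maximum
temperature is an annual sinusoid peaking August 1 plus iid Gaussian noise,
calibrated to a 16.9 degC annual mean, a 26.5 degC warm-season mean and an
overall SD near 10 degC; counts are drawn per cause and day with mean

$$
\mu_{tj} = \mathrm{baseline}_j \times \mathrm{dow}_t \times
  \exp\!\big(\delta\,\mathrm{year}_t + \gamma^\top x_t +
  \beta_j \max(0, T_t - \theta^\ast)\big)
$$

and variance exactly $\phi\mu$ (negative binomial with size
$\mu/(\phi-1)$; exact Poisson at $\phi = 1$). Defaults: an all-cause
baseline of 98.67 deaths/day down to a rare cause at 0.07/day, $\phi = 1.5$
for causes with baseline $\ge 1$ and $1.0$ for rare causes (dispersion of
rare series is weakly identified, so the placeholder is conservative),
$\beta = 0.0296$ ($RR\ 1.03$), a $-0.5\%$/year trend, and small
humidity/pressure effects on centred covariates so baselines keep their
daily-mean interpretation.

Two generator choices deserve emphasis. First, the true threshold
$\theta^\ast$ defaults to 30.1 degC, the 90th percentile of the generator's
own temperature climate: a single sinusoid cannot simultaneously match a
16.9 degC annual mean, a 26.5 degC warm-season mean *and* an arbitrary
externally chosen percentile (real summers are monsoon-flattened), so the
generator is made internally consistent — the analysis percentile and the
generative threshold coincide, which is exactly the regime the estimator
assumes. Second, counts are drawn by inverse-CDF transform of one uniform
per day and cause, so two configs differing only in $\beta$ produce
bit-identical counts on sub-threshold days under the same seed — a sharp
invariance that ordinary `rnbinom()` calls (whose uniform consumption
varies with the parameters) would not give.

What the generator does not emulate: mortality displacement (harvesting),
heat-wave duration effects beyond the daily excess, spatial heterogeneity
(one implicit station), autocorrelated weather beyond the seasonal cycle,
and hierarchical nesting of causes (each series is drawn independently, so
a sub-category can exceed its parent on a given day — the wide-format
validator therefore makes the nesting check opt-in). Passing recovery tests
on these data shows the estimator is consistent under the stated model, not
that real-data biases (lag misspecification, unmeasured confounding) are
absent.

## Numerical choices and degenerate inputs

* IRLS convergence: relative deviance change below $10^{-8}$ or 100
  iterations; non-convergence is flagged on the result, never silent.
* Rank-deficient designs (e.g. a heat column that is identically zero
  because no day exceeds $\theta$, or an all-constant pollutant column) are
  an error naming the collinear columns, never a silent drop.
* "Above the threshold" is strict ($T > \theta$); ties at $\theta$ carry
  zero excess either way, so the convention only affects the exceedance-day
  census.
* Display percentages round half away from zero at two decimals, the
  convention of published tables; machine outputs keep full precision and
  every display number is recomputable from them.
* The scatter-plot smoother is locally weighted linear regression with
  tricube weights; at span 1.0 each window spans all points, windows with a
  single distinct abscissa fall back to the weighted mean, and the
  RR-versus-log10(AD) display excludes causes whose 95% CI includes 1 or
  whose AD is non-positive (the log scale requires positivity).
* ICD-10 codes match the taxonomy at letter-plus-two-digit stem resolution;
  sub-decimal characters are truncated first. Overlap is intentional:
  self-harm (X60-X84) is counted both under its own label and inside the
  external-causes block, and cause labels are modelled as independent
  series, so attributable deaths are not additive across labels.

## Problem sizes used in the tests

The recovery study simulates 200 replicates of the full 18-year design
(6,575 days; 2,754 warm-season days) with $\beta = 0.0296$, baseline 98.67
and $\phi = 1.5$, requiring the mean slope within 10% of truth and 95%
Wald coverage within three binomial standard errors of nominal. The
threshold-direction study uses 50 replicates across the 90/93/95/99th
percentiles. Moment checks on the dispersion machinery use a 28-year
constant-climate series (about 10,000 days). Taxonomy membership is checked
against brute-force enumeration of all 2,600 letter+two-digit stems.

## Known limitations

The model estimates a single city-wide slope per cause: no effect
modification by age or sex, no distributed-lag structure beyond simple
shifts and a 3-day moving average, no harvesting adjustment, and no
uncertainty interval on $AD$ (the delta-method interval would ignore the
day-to-day dependence of $AF_t$ on a single $\hat\beta$; a bootstrap is the
natural extension). The threshold is shared across causes although
cause-specific thresholds are biologically plausible. These are properties
of the estimand the package implements, not implementation shortcuts.
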