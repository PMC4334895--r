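Package: heatmort
Title: Heat-Attributable Mortality from Daily Temperature-Mortality Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the mortality burden of high ambient
    temperature from city-level daily time series. Fits overdispersed
    (quasi-Poisson) regressions of daily cause-specific death counts on the
    excess of daily maximum temperature above a percentile-based threshold,
    adjusting for humidity, air pressure, day of week, long-term trends and
    optionally air pollutants; converts the fitted heat slope into day-level
    attributable fractions and cause-specific attributable-death totals; and
    sweeps lag structures and threshold percentiles in sensitivity analyses.
    Includes an ICD-10 cause-of-death taxonomy utility and a synthetic-data
    generator that emulates an 18-year warm-season study design with a known,
    recoverable threshold exposure-response.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: splines, stats, tools, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
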