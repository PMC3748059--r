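Package: aedesclim
Title: Climate-Driven Temporal Dynamics of Aedes aegypti Trap Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of weekly Aedes aegypti sticky-trap surveillance series
    against meteorological covariates. Provides negative-binomial generalized
    linear models with lagged covariates, a temperature-by-humidity interaction
    and an autoregressive per-trap abundance term (with trap-effort offset and
    no intercept); univariate lag screening and AIC model selection; derivation
    of interaction sign-change thresholds and temperature/humidity population-
    growth regions; one-step and iterated out-of-fit forecasting scored by
    Spearman rank correlation; and a Morlet continuous wavelet suite (power
    spectrum with red-noise chi-squared significance and cone of influence,
    cross-wavelet spectrum with phase, smoothed wavelet coherence with
    surrogate-based significance). A synthetic-data module generates seasonal
    climate series and climate-forced overdispersed trap counts with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
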