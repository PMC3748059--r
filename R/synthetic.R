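# Synthetic weekly climate and climate-forced trap counts.
#
# The generator is the generative mirror of the fitted count model: seasonal
# AR(1)-noise climate series feed a negative-binomial count recursion through
# lagged minimum temperature, lagged minimum humidity, their interaction and
# the previous week's per-trap abundance. Defaults reproduce the surveillance
# conditions the analysis assumes: ~90 weekly observations, minimum
# temperature averaging 19.36 C, minimum humidity averaging 55.93% (the most
# variable humidity summary), roughly 35 of 90 rain-free weeks, wind around
# 2.9 m/s, ~425 traps, mean per-trap abundance ~0.58 and strongly
# overdispersed counts.

# evaluate expr under a temporary RNG state when seed is given
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# stationary Gaussian AR(1) noise
ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  if (n > 1) for (t in 2:n) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, sd)
  x
}

#' Parameters of the synthetic climate generator
#'
#' Each variable is a seasonal mean plus a cosine annual cycle (period
#' `period` weeks, warm-season peak at `peak_week`) plus stationary AR(1)
#' noise. Minimum temperature and minimum humidity are generated directly
#' (they are the covariates that force the count model); the average and
#' maximum summaries are built as positive offsets ("gaps") above them, which
#' enforces the per-week orderings by construction. Precipitation is a
#' seasonal dry-week Bernoulli (dry odds peak in winter) with Gamma rainfall
#' in wet weeks; humidity is clipped to `[0, 100]` and wind to non-negative
#' values.
#'
#' @param tmin_mean,tmin_amp,tmin_sd minimum-temperature seasonal mean (C),
#'   cosine amplitude and AR(1) innovation sd.
#' @param hmin_mean,hmin_amp,hmin_sd analogous for minimum humidity (%).
#' @param tavg_gap,tmax_gap,havg_gap,hmax_gap mean positive offsets giving
#'   tavg = tmin + gap, tmax = tavg + gap (and likewise for humidity).
#' @param gap_sd sd of the weekly gap noise (gaps are truncated at 0.5).
#' @param wind_mean,wind_amp,wind_sd,wind_phi wind speed model (m/s).
#' @param phi AR(1) coefficient of the temperature/humidity noise, `|phi|<1`.
#' @param period,peak_week length of the seasonal cycle in weeks and the week
#'   of its warm peak.
#' @param dry_logit_mean,dry_logit_amp logistic-scale mean and winter-peaking
#'   amplitude of the weekly dry (zero-rain) probability.
#' @param rain_mean_wet,rain_shape Gamma mean (mm, modulated seasonally) and
#'   shape of rainfall in wet weeks.
#' @param seed optional integer seed; generation is deterministic given it.
#' @return a validated list of class `climate_params`.
#' @export
climate_params <- function(tmin_mean = 19.36, tmin_amp = 2.0, tmin_sd = 1.0,
                           hmin_mean = 55.93, hmin_amp = 8.0, hmin_sd = 3.0,
                           tavg_gap = 5.0, tmax_gap = 5.5,
                           havg_gap = 20.3, hmax_gap = 15.1,
                           gap_sd = 0.8,
                           wind_mean = 2.9, wind_amp = 0.5, wind_sd = 0.5,
                           wind_phi = 0.5,
                           phi = 0.6, period = 52, peak_week = 3,
                           dry_logit_mean = -0.9, dry_logit_amp = 1.8,
                           rain_mean_wet = 100, rain_shape = 1.2,
                           seed = NULL) {
  p <- as.list(environment())
  stopifnot(abs(p$phi) < 1, abs(p$wind_phi) < 1,
            p$tmin_sd >= 0, p$hmin_sd >= 0, p$wind_sd >= 0, p$gap_sd >= 0,
            p$tmin_amp >= 0, p$hmin_amp >= 0, p$wind_amp >= 0,
            p$tavg_gap >= 0, p$tmax_gap >= 0, p$havg_gap >= 0,
            p$hmax_gap >= 0, p$rain_mean_wet > 0, p$rain_shape > 0,
            p$period >= 2)
  class(p) <- "climate_params"
  p
}

#' Generate a synthetic weekly climate series
#'
#' @param p a [climate_params()] object.
#' @param n_weeks number of weeks to generate (>= 10).
#' @param start_week first epidemiological week label.
#' @return a [meteo_series()].
#' @examples
#' m <- generate_climate(climate_params(seed = 1), 90)
#' mean(m$tmin_c)
#' @export
generate_climate <- function(p, n_weeks, start_week = "2009-W11") {
  stopifnot(inherits(p, "climate_params"), n_weeks >= 10)
  with_seed(p$seed, {
    t <- seq_len(n_weeks)
    season <- cos(2 * pi * (t - p$peak_week) / p$period)

    tmin <- p$tmin_mean + p$tmin_amp * season + ar1_noise(n_weeks, p$phi, p$tmin_sd)
    gap1 <- pmax(0.5, stats::rnorm(n_weeks, p$tavg_gap, p$gap_sd))
    gap2 <- pmax(0.5, stats::rnorm(n_weeks, p$tmax_gap, p$gap_sd))
    tavg <- tmin + gap1
    tmax <- tavg + gap2

    hmin <- p$hmin_mean + p$hmin_amp * season + ar1_noise(n_weeks, p$phi, p$hmin_sd)
    hgap1 <- pmax(0.5, stats::rnorm(n_weeks, p$havg_gap, 2 * p$gap_sd))
    hgap2 <- pmax(0.5, stats::rnorm(n_weeks, p$hmax_gap, 1.5 * p$gap_sd))
    hmin <- pmax(hmin, 0)
    havg <- hmin + hgap1
    hmax <- havg + hgap2
    # clip at 100 from the top down so the ordering survives
    hmax <- pmin(hmax, 100)
    havg <- pmin(havg, hmax)
    hmin <- pmin(hmin, havg)

    # dry-week probability peaks half a cycle after the warm peak (winter)
    p_dry <- stats::plogis(p$dry_logit_mean - p$dry_logit_amp * season)
    dry <- stats::runif(n_weeks) < p_dry
    rain_mean <- p$rain_mean_wet * (0.25 + 0.75 * (season + 1) / 2)
    amount <- stats::rgamma(n_weeks, shape = p$rain_shape,
                            rate = p$rain_shape / rain_mean)
    precip <- ifelse(dry, 0, amount)

    wind <- pmax(0, p$wind_mean + p$wind_amp * season +
                   ar1_noise(n_weeks, p$wind_phi, p$wind_sd))

    meteo_series(week_seq(start_week, n_weeks), precip, tmin, tavg, tmax,
                 hmin, havg, hmax, wind)
  })
}

#' Parameters of the synthetic trap-count generator
#'
#' Counts follow the negative-binomial recursion
#' \deqn{y_t \sim NB(\mu_t, \theta), \quad
#'   \mu_t = N_t \exp(\beta_{ar} a_{t-1} + \beta_T T_{t-\ell_T} +
#'   \beta_H H_{t-\ell_H} + \beta_{int} T_{t-\ell_T} H_{t-\ell_H})}
#' where \eqn{N_t} is the number of observed traps, \eqn{T} is minimum
#' temperature, \eqn{H} minimum humidity and \eqn{a_t = y_t /
#' \mathrm{positive\_traps}_t} the per-trap abundance. The negative-binomial
#' parameterization is mean \eqn{\mu} and size \eqn{\theta} with variance
#' \eqn{\mu + \mu^2/\theta} (two conventions exist; this one makes a single
#' overdispersion parameter around 19 produce the observed variance-to-mean
#' ratio). Positive traps are drawn as
#' `1 + Binomial(observed - 1, 1 - exp(-pos_calib * mu/observed))`, a
#' clustered-occupancy approximation whose calibration constant keeps the
#' positive fraction interior and the mean per-trap abundance near 0.58.
#' Coefficient defaults are the headline fitted values of the analysis this
#' generator mirrors.
#'
#' @param beta_ar coefficient of the previous week's per-trap abundance.
#' @param beta_temp,lag_temp minimum-temperature coefficient and lag (weeks).
#' @param beta_hum,lag_hum minimum-humidity coefficient and lag (weeks).
#' @param beta_int interaction (temperature x humidity) coefficient.
#' @param theta overdispersion parameter, > 0.
#' @param n_traps traps installed; weekly inspected counts are
#'   `Binomial(n_traps, inspect_prob)`.
#' @param inspect_prob weekly probability a trap is inspected.
#' @param pos_calib calibration constant of the positive-trap model.
#' @param a0 initial per-trap abundance (> 0).
#' @param burn_in weeks discarded so the recursion forgets `a0`; must exceed
#'   the largest lag.
#' @param seed optional integer seed.
#' @return a validated list of class `mosquito_params`.
#' @export
mosquito_params <- function(beta_ar = 0.8344, beta_temp = -0.0714,
                            beta_hum = -0.0257, beta_int = 0.0016,
                            theta = 19.11, lag_temp = 4, lag_hum = 2,
                            n_traps = 425, inspect_prob = 0.97,
                            pos_calib = 5.1, a0 = 0.58, burn_in = 12,
                            seed = NULL) {
  p <- as.list(environment())
  stopifnot(p$theta > 0, p$a0 > 0,
            p$lag_temp %in% 0:4, p$lag_hum %in% 0:4,
            p$n_traps >= 1, p$inspect_prob > 0, p$inspect_prob <= 1,
            p$pos_calib > 0, p$burn_in > max(p$lag_temp, p$lag_hum))
  class(p) <- "mosquito_params"
  p
}

#' Generate climate-forced overdispersed trap counts
#'
#' Runs the count recursion of [mosquito_params()] over a climate series and
#' discards the burn-in, so the returned series starts `burn_in` weeks into
#' the climate axis with all its lagged forcings defined.
#'
#' @param climate a `meteo_series` longer than `burn_in + max(lags)`.
#' @param p a [mosquito_params()] object.
#' @return an [entomo_series()] of `nrow(climate) - burn_in` weeks.
#' @export
generate_counts <- function(climate, p) {
  stopifnot(inherits(climate, "meteo_series"), inherits(p, "mosquito_params"))
  n <- nrow(climate)
  maxlag <- max(p$lag_temp, p$lag_hum)
  if (n <= p$burn_in + maxlag) {
    stop("climate series must be longer than burn_in + max lag")
  }
  with_seed(p$seed, {
    tmin <- climate$tmin_c
    hmin <- climate$hmin_pct
    observed <- pmax(1L, stats::rbinom(n, p$n_traps, p$inspect_prob))
    y <- integer(n)
    pos <- integer(n)
    a <- rep(p$a0, n)
    start_t <- maxlag + 1L
    if (start_t < 2L) start_t <- 2L
    for (t in start_t:n) {
      eta <- p$beta_ar * a[t - 1] +
        p$beta_temp * tmin[t - p$lag_temp] +
        p$beta_hum * hmin[t - p$lag_hum] +
        p$beta_int * tmin[t - p$lag_temp] * hmin[t - p$lag_hum]
      if (abs(eta) > 30) {
        stop("linear predictor |eta| > 30 at week ", climate$week[t],
             "; rescale the generator coefficients")
      }
      mu <- observed[t] * exp(eta)
      y[t] <- stats::rnbinom(1, size = p$theta, mu = mu)
      rho <- mu / observed[t]
      pos[t] <- 1L + stats::rbinom(1, observed[t] - 1L,
                                   1 - exp(-p$pos_calib * rho))
      a[t] <- y[t] / pos[t]
    }
    keep <- (p$burn_in + 1L):n
    entomo_series(climate$week[keep], y[keep], pos[keep], observed[keep])
  })
}

#' Simulate a complete surveillance dataset
#'
#' Convenience wrapper: generates `n_weeks + burn_in` weeks of climate,
#' forces the count recursion through it, and aligns the two series. When
#' `seed` is given it overrides the component seeds (`seed` for the climate,
#' `seed + 1` for the counts).
#'
#' @param n_weeks length of the returned aligned dataset.
#' @param climate a [climate_params()] object.
#' @param mosquito a [mosquito_params()] object.
#' @param start_week label of the first climate week (the aligned dataset
#'   starts `burn_in` weeks later).
#' @param seed optional integer master seed.
#' @return a list with elements `data` (an `aedes_dataset`), `entomo`,
#'   `climate` (the full climate series including burn-in).
#' @examples
#' sim <- simulate_surveillance(30, seed = 42)
#' summarize_weekly(sim$data)$counts$mean
#' @export
simulate_surveillance <- function(n_weeks = 90,
                                  climate = climate_params(),
                                  mosquito = mosquito_params(),
                                  start_week = "2009-W11", seed = NULL) {
  stopifnot(n_weeks >= 6)
  if (!is.null(seed)) {
    climate$seed <- seed
    mosquito$seed <- seed + 1L
  }
  met <- generate_climate(climate, n_weeks + mosquito$burn_in, start_week)
  ent <- generate_counts(met, mosquito)
  d <- align_weekly(ent, met)
  list(data = d, entomo = ent, climate = met)
}
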