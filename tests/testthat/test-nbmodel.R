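test_that("design matrix drops lagged rows and builds interactions exactly", {
  sim <- simulate_surveillance(90, seed = 101)
  d <- sim$data
  spec <- nb_model_spec(list(c("tmin", 4), c("hmin", 2)),
                        interactions = list(c("tmin", "hmin")), ar = TRUE)
  ds <- build_design(d, spec)
  expect_equal(nrow(ds$X), 86)  # max lag 4 drops the first 4 of 90 weeks
  expect_equal(ds$rows_used, 5:90)
  expect_equal(colnames(ds$X),
               c("tmin_l4", "hmin_l2", "tmin_l4_x_hmin_l2", "ar1"))
  # interaction column is the elementwise product of the lagged columns
  t <- 20
  i <- which(ds$rows_used == t)
  expect_equal(unname(ds$X[i, "tmin_l4_x_hmin_l2"]),
               d$tmin_c[t - 4] * d$hmin_pct[t - 2])
  expect_equal(unname(ds$X[i, "ar1"]), d$abundance[t - 1])
  expect_equal(ds$offset, log(d$observed_traps[5:90]))

  ar_only <- build_design(d, nb_model_spec(ar = TRUE))
  expect_equal(nrow(ar_only$X), 89)

  expect_error(nb_model_spec(list(c("temperature", 1))), "unknown variable")
  expect_error(nb_model_spec(list(c("tmin", 0), c("tmax", 2))),
               "at most one temperature")
  expect_error(nb_model_spec(list(c("tmin", 0)),
                             interactions = list(c("tmin", "hmin"))),
               "interactions must pair")
})

test_that("single-covariate closed form: beta-hat = log(mean(y)/N)", {
  # all-ones covariate with constant offset log(N): the NB score equation
  # reduces to sum(y - mu) = 0, so mu-hat = mean(y) exactly
  set.seed(7)
  n <- 80
  N <- 425L
  y <- rnbinom(n, size = 10, mu = N * exp(-0.4))
  d <- structure(data.frame(week = week_seq("2010-W01", n),
                            total_captures = y,
                            positive_traps = pmax(1L, pmin(N, y)),
                            observed_traps = N,
                            tmin_c = 1, abundance = y / pmax(1L, pmin(N, y))),
                 class = c("aedes_dataset", "data.frame"))
  d$precip_mm <- 0; d$tavg_c <- 1; d$tmax_c <- 1
  d$hmin_pct <- 1; d$havg_pct <- 1; d$hmax_pct <- 1; d$wind_ms <- 1
  f <- fit_nb(build_design(d, nb_model_spec(list(c("tmin", 0)), ar = FALSE)))
  expect_equal(f$coefficients$estimate[1], log(mean(y) / N), tolerance = 1e-6)
})

test_that("fit agrees with an independent optimizer of the same likelihood", {
  sim <- simulate_surveillance(60, seed = 103)
  spec <- nb_model_spec(list(c("tmin", 4), c("hmin", 2)), ar = TRUE)
  ds <- build_design(sim$data, spec)
  f <- fit_nb(ds)
  o <- optim(c(f$coefficients$estimate * 0, log(10)), nb_loglik_direct,
             nb_score_direct, X = ds$X, y = ds$y, off = ds$offset,
             control = list(fnscale = -1, maxit = 10000, reltol = 1e-14),
             method = "BFGS")
  expect_equal(unname(o$par[1:3]), f$coefficients$estimate, tolerance = 1e-4)
  expect_equal(exp(o$par[4]), f$theta, tolerance = 1e-3)
  expect_equal(o$value, f$loglik, tolerance = 1e-6)
  # AIC bookkeeping counts theta as a parameter
  expect_equal(f$aic, -2 * f$loglik + 2 * (3 + 1))
  expect_equal(length(f$fitted), length(ds$y))
  expect_true(all(f$fitted > 0))
})

test_that("nested models cannot increase deviance at fixed theta", {
  sim <- simulate_surveillance(80, seed = 104)
  small <- build_design(sim$data, nb_model_spec(list(c("tmin", 4)), ar = TRUE),
                        align_lag = 4)
  big <- build_design(sim$data,
                      nb_model_spec(list(c("tmin", 4), c("hmin", 2)),
                                    ar = TRUE), align_lag = 4)
  f_small <- fit_nb(small, theta = 19.11)
  f_big <- fit_nb(big, theta = 19.11)
  expect_lte(f_big$deviance, f_small$deviance + 1e-8)
})

test_that("a useless extra column raises AIC on average", {
  diffs <- vapply(1:20, function(i) {
    tryCatch({
      sim <- simulate_surveillance(80, seed = 600 + i)
      base <- nb_model_spec(list(c("tmin", 4), c("hmin", 2)),
                            interactions = list(c("tmin", "hmin")), ar = TRUE)
      extra <- nb_model_spec(list(c("tmin", 4), c("hmin", 2), c("wind", 3)),
                             interactions = list(c("tmin", "hmin")), ar = TRUE)
      fb <- fit_nb(build_design(sim$data, base, align_lag = 4))
      fe <- fit_nb(build_design(sim$data, extra, align_lag = 4))
      fe$aic - fb$aic
    }, error = function(e) NA_real_)
  }, 0)
  expect_gte(sum(!is.na(diffs)), 15)
  expect_gt(mean(diffs, na.rm = TRUE), 0)  # expected penalty 2 - E[chisq_1] = 1
})

test_that("Wald intervals cover the generating interaction coefficient", {
  spec <- nb_model_spec(list(c("tmin", 4), c("hmin", 2)),
                        interactions = list(c("tmin", "hmin")), ar = TRUE)
  cover <- vapply(1:60, function(i) {
    f <- tryCatch(
      fit_nb(build_design(simulate_surveillance(90, seed = 7000 + i)$data,
                          spec)),
      error = function(e) NULL)
    if (is.null(f)) return(NA)
    cf <- f$coefficients[f$coefficients$term == "tmin_l4_x_hmin_l2", ]
    abs(cf$estimate - 0.0016) < qnorm(0.975) * cf$se
  }, NA)
  expect_gt(mean(cover, na.rm = TRUE), 0.85)
  expect_lte(mean(cover, na.rm = TRUE), 1.0)
})

test_that("ACF/PACF recover AR(1) structure and normalize at lag zero", {
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = 0.8), 2000))
  r <- acf_pacf(x, max_lag = 10)
  expect_equal(r$acf[1], 1)            # ACF(0) = 1 exactly
  expect_lt(abs(r$acf[2] - 0.8), 0.05) # ACF(1) ~ phi
  expect_lt(abs(r$acf[4] - 0.8^3), 0.08)
  expect_lt(abs(r$pacf[1] - 0.8), 0.05)
  expect_lt(max(abs(r$pacf[3:10])), 3 * r$band)  # ~0 beyond lag 1
  expect_equal(r$band, 1.96 / sqrt(2000), tolerance = 1e-3)
  expect_error(acf_pacf(rep(1, 50)), "constant")
  # white noise stays inside the bands almost everywhere
  set.seed(4)
  w <- acf_pacf(rnorm(500), max_lag = 20)
  expect_gt(mean(abs(w$acf[-1]) < w$band), 0.8)
})

test_that("screening ranks the active lag first and tolerates empty results", {
  # only tmin at lag 4 forces the counts; the temperature anomaly is
  # centered (mean 0) so the intercept-free screen can discriminate lags
  hits <- vapply(1:10, function(i) {
    cl <- climate_params(tmin_mean = 0, seed = 800 + i)
    p <- mosquito_params(beta_ar = 0, beta_hum = 0, beta_int = 0,
                         beta_temp = 0.08, seed = 900 + i)
    sim <- simulate_surveillance(90, climate = cl, mosquito = p)
    s <- univariate_screen(sim$data, variables = "tmin", alpha = 0.05)
    nrow(s) > 0 && s$lag[1] == 4
  }, NA)
  expect_gte(sum(hits), 7)  # best lag identified in most replicates

  # nothing significant: empty table, no error
  d <- null_dataset(seed = 55)
  s0 <- univariate_screen(d, variables = "wind", alpha = 1e-8)
  expect_equal(nrow(s0), 0)
  expect_s3_class(s0, "screen_table")
})

test_that("model selection fits the temperature x humidity grid by AIC", {
  sim <- simulate_surveillance(90, seed = 117)
  s <- univariate_screen(sim$data)
  sel <- select_model(sim$data, s)
  expect_s3_class(sel$best, "nbfit")
  expect_lte(nrow(sel$ranking), 9)
  # ranking is sorted and consistent with the per-fit AICs
  aics <- sel$ranking$aic[!is.na(sel$ranking$aic)]
  expect_true(!is.unsorted(aics))
  expect_equal(sel$best$aic, aics[1])
  expect_equal(vapply(sel$fits, function(f) f$aic, 0), aics)
  # all candidates share one sample so AICs are comparable
  rows <- lapply(sel$fits, function(f) f$rows_used)
  expect_true(all(vapply(rows, identical, NA, rows[[1]])))
  # screening must retain both variable families
  expect_error(select_model(sim$data, univariate_screen(sim$data,
                                                        variables = "wind")),
               "at least one temperature")
})

test_that("selection recovers the generating covariate pair most of the time", {
  picks <- vapply(1:7, function(i) {
    sim <- simulate_surveillance(90, seed = 4000 + i)
    sel <- tryCatch(select_model(sim$data, univariate_screen(sim$data)),
                    error = function(e) NULL)
    if (is.null(sel)) return(NA_character_)
    paste(sel$ranking$temp_var[1], sel$ranking$hum_var[1])
  }, "")
  expect_gte(sum(picks == "tmin hmin", na.rm = TRUE), 4)
})

test_that("forecasting scores by Spearman and respects its contracts", {
  expect_equal(spearman_rank(1:10, (1:10)^2), 1)   # monotone agreement
  expect_equal(spearman_rank(1:10, -(1:10)), -1)   # reversed ranks
  sim <- simulate_surveillance(109, seed = 118)
  fit_window <- sim$data[1:90, ]
  class(fit_window) <- class(sim$data)
  spec <- nb_model_spec(list(c("tmin", 4), c("hmin", 2)),
                        interactions = list(c("tmin", "hmin")), ar = TRUE)
  f <- fit_nb(build_design(fit_window, spec))
  fc1 <- forecast_nb(f, sim$data, origin = 90, horizon = 19)
  expect_equal(nrow(fc1$pred), 19)
  expect_true(all(fc1$pred$mu > 0))
  expect_true(all(fc1$pred$lwr <= fc1$pred$upr))
  expect_true(fc1$src >= -1 && fc1$src <= 1)
  fc2 <- forecast_nb(f, sim$data, origin = 90, horizon = 19,
                     mode = "iterated")
  expect_false(identical(fc1$pred$mu, fc2$pred$mu))
  expect_error(forecast_nb(f, sim$data, origin = 90, horizon = 30),
               "missing future meteorology")
})

test_that("one-step forecasts of model-generated hold-outs rank well", {
  # hold-out generated by the same process: SRC should sit well above zero
  src <- vapply(1:5, function(i) {
    sim <- simulate_surveillance(109, seed = 5200 + i)
    fw <- sim$data[1:90, ]
    class(fw) <- class(sim$data)
    spec <- nb_model_spec(list(c("tmin", 4), c("hmin", 2)),
                          interactions = list(c("tmin", "hmin")), ar = TRUE)
    f <- fit_nb(build_design(fw, spec))
    forecast_nb(f, sim$data, origin = 90, horizon = 19)$src
  }, 0)
  expect_gt(mean(src), 0.3)
})
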