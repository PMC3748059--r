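#' Configuration of the end-to-end analysis pipeline
#'
#' @param entomo_path,meteo_path optional CSV inputs (see [read_entomo()]).
#'   When `NULL`, data are simulated with the synthetic generator.
#' @param n_weeks simulated fitted-window length (ignored when reading
#'   files).
#' @param climate,mosquito generator parameter objects for simulation.
#' @param alpha screening significance level, in (0, 1).
#' @param lags lag range screened, subset of `0..4`.
#' @param scenarios previous-week per-trap abundances of the growth-region
#'   scenarios.
#' @param horizon forecast horizon in weeks (>= 1).
#' @param forecast_mode `"one_step"` or `"iterated"`.
#' @param wavelet_dj,wavelet_s0 CWT resolution parameters.
#' @param n_surrogates coherence surrogate count.
#' @param level confidence level used throughout.
#' @param seed master seed; each stochastic stage derives its own seed from
#'   it by a fixed offset.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(entomo_path = NULL, meteo_path = NULL,
                            n_weeks = 90,
                            climate = climate_params(),
                            mosquito = mosquito_params(),
                            alpha = 0.05, lags = 0:4,
                            scenarios = c(low = 0.111, middle = 0.56,
                                          high = 0.99),
                            horizon = 19,
                            forecast_mode = c("one_step", "iterated"),
                            wavelet_dj = 1 / 12, wavelet_s0 = 2,
                            n_surrogates = 300, level = 0.95, seed = 1L) {
  forecast_mode <- match.arg(forecast_mode)
  cfg <- as.list(environment())
  if (cfg$horizon < 1) stop("horizon must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (!all(cfg$lags %in% 0:4)) stop("lags must be within 0..4")
  if (any(cfg$scenarios <= 0)) stop("scenario abundances must be > 0")
  if (xor(is.null(cfg$entomo_path), is.null(cfg$meteo_path))) {
    stop("provide both entomo_path and meteo_path, or neither")
  }
  for (p in c(cfg$entomo_path, cfg$meteo_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipe_log <- function(con, ...) {
  msg <- paste0(...)
  message(msg)
  if (!is.null(con)) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg), con)
  }
  invisible(msg)
}

run_stage <- function(name, con, expr) {
  pipe_log(con, "stage ", name, ": start")
  tryCatch(expr, error = function(e) {
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full surveillance analysis pipeline
#'
#' Sequences the analysis end to end: simulate (or read) the weekly tables,
#' summarize them, screen lagged covariates univariately, select the
#' temperature-by-humidity interaction model by AIC, derive sign-change
#' thresholds and growth regions for the configured abundance scenarios,
#' forecast the hold-out window and score it by Spearman rank correlation,
#' and run the wavelet suite (abundance power spectrum with red-noise
#' significance; cross-wavelet of abundance against the selected temperature
#' and humidity covariates and their interaction series; coherence of
#' abundance with the interaction series). Every stage logs its parameters
#' and persists its artifacts under `out_dir` as it completes, so a failing
#' stage leaves the earlier outputs in place; the run is deterministic given
#' `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return the summary list (also serialized to `summary.json`), invisibly
#'   containing the screening table, candidate ranking, best-fit
#'   coefficients, thresholds, scenario frontiers and forecast score.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(con))
  seed <- as.integer(config$seed)

  dat <- run_stage("data", con, {
    if (!is.null(config$entomo_path)) {
      ent <- read_entomo(config$entomo_path)
      met <- read_meteo(config$meteo_path)
      full <- align_weekly(ent, met)
      pipe_log(con, "  read ", nrow(full), " aligned weeks from files")
      full
    } else {
      n_total <- config$n_weeks + config$horizon
      sim <- simulate_surveillance(n_total, config$climate, config$mosquito,
                                   seed = seed)
      write_entomo(sim$entomo, file.path(out_dir, "entomo.csv"))
      write_meteo(sim$climate, file.path(out_dir, "climate.csv"))
      pipe_log(con, "  simulated ", n_total, " weeks (seed ", seed, ")")
      sim$data
    }
  })
  n_fit <- nrow(dat) - config$horizon
  if (n_fit < 10) stop("stage data failed: series too short for the horizon")
  fit_window <- dat[seq_len(n_fit), ]
  class(fit_window) <- class(dat)

  summ <- run_stage("summary", con, summarize_weekly(fit_window))

  screened <- run_stage("screen", con, {
    s <- univariate_screen(fit_window, lags = config$lags,
                           alpha = config$alpha)
    utils::write.csv(as.data.frame(s), file.path(out_dir, "screening.csv"),
                     row.names = FALSE)
    pipe_log(con, "  ", nrow(s), " significant (variable, lag) pairs at alpha = ",
             config$alpha)
    s
  })

  sel <- run_stage("select", con, {
    sl <- select_model(fit_window, screened)
    utils::write.csv(sl$ranking, file.path(out_dir, "candidates.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(week = sl$best$weeks,
                                fitted = sl$best$fitted,
                                resid_deviance = sl$best$residuals_deviance,
                                resid_pearson = sl$best$residuals_pearson),
                     file.path(out_dir, "residuals.csv"), row.names = FALSE)
    pipe_log(con, "  ", sum(!is.na(sl$ranking$aic)), " of ",
             nrow(sl$ranking), " candidates fitted; best AIC = ",
             sprintf("%.2f", sl$best$aic))
    sl
  })

  thres <- run_stage("thresholds", con, {
    th <- sign_change_thresholds(sel$best)
    maps <- lapply(config$scenarios, function(yp) growth_map(sel$best, yp))
    for (nm in names(maps)) {
      write_growth_map(maps[[nm]], sel$best,
                       file.path(out_dir, paste0("growth_", nm, ".csv")),
                       file.path(out_dir, paste0("growth_", nm, ".json")))
    }
    list(pair = th, maps = maps)
  })

  fc <- run_stage("forecast", con, {
    f <- forecast_nb(sel$best, dat, origin = n_fit,
                     horizon = config$horizon, mode = config$forecast_mode,
                     level = config$level)
    utils::write.csv(f$pred, file.path(out_dir, "forecast.csv"),
                     row.names = FALSE)
    pipe_log(con, "  Spearman rank correlation = ", sprintf("%.4f", f$src))
    f
  })

  wav <- run_stage("wavelet", con, {
    tvar <- meteo_vars[[sub("_l[0-9]$", "", sel$best$roles$temp)]]
    hvar <- meteo_vars[[sub("_l[0-9]$", "", sel$best$roles$hum)]]
    cw_args <- list(dt = 1, dj = config$wavelet_dj, s0 = config$wavelet_s0)
    cwt_of <- function(x, off = 0) do.call(cwt_morlet,
                                           c(list(preprocess(x, off)), cw_args))
    ab <- cwt_of(fit_window$abundance,
                 off = if (any(fit_window$abundance <= 0)) 0.01 else 0)
    sig <- red_noise_significance(ab, level = config$level)
    write_spectrum_csv(ab, file.path(out_dir, "power_abundance.csv"),
                       mask = sig, weeks = fit_window$week)
    ct <- cwt_of(fit_window[[tvar]])
    ch <- cwt_of(fit_window[[hvar]])
    ci <- do.call(cwt_morlet,
                  c(list(interaction_series(fit_window[[tvar]],
                                            fit_window[[hvar]])), cw_args))
    for (nm in c("temp", "hum", "interaction")) {
      other <- switch(nm, temp = ct, hum = ch, interaction = ci)
      xw <- cross_wavelet(ab, other)
      write_spectrum_csv(xw, file.path(out_dir, paste0("xwt_", nm, ".csv")),
                         weeks = fit_window$week)
    }
    wtc <- coherence(ab, ci, n_surrogates = config$n_surrogates,
                     level = config$level, seed = seed + 1000L)
    write_spectrum_csv(wtc, file.path(out_dir, "coherence_interaction.csv"),
                       weeks = fit_window$week)
    pipe_log(con, "  wavelet suite done (", config$n_surrogates,
             " coherence surrogates)")
    list(r1 = sig$r1,
         power_sig_frac = mean(sig$mask[ab$in_coi]),
         coherence_sig_frac = if (is.null(wtc$mask)) NA
                              else mean(wtc$mask[wtc$in_coi]))
  })

  best_cf <- sel$best$coefficients
  summary <- list(
    config = list(n_weeks = n_fit, horizon = config$horizon,
                  alpha = config$alpha, lags = config$lags,
                  scenarios = as.list(config$scenarios),
                  forecast_mode = config$forecast_mode,
                  wavelet = list(dj = config$wavelet_dj,
                                 s0 = config$wavelet_s0,
                                 n_surrogates = config$n_surrogates),
                  level = config$level, seed = seed,
                  simulated = is.null(config$entomo_path)),
    data_summary = summ,
    screening = as.data.frame(screened),
    candidates = sel$ranking[, c("temp_var", "temp_lag", "hum_var",
                                 "hum_lag", "aic", "deviance")],
    best_model = list(coefficients = best_cf, theta = sel$best$theta,
                      aic = sel$best$aic, deviance = sel$best$deviance,
                      loglik = sel$best$loglik),
    thresholds = list(h_star = thres$pair$h_star, t_star = thres$pair$t_star),
    scenario_growth = lapply(thres$maps, function(m) {
      list(y_prev = m$y_prev, growth_fraction = mean(m$growth),
           min_frontier_hum = if (all(is.na(m$frontier))) NA
                              else min(m$frontier, na.rm = TRUE))
    }),
    forecast = list(src = fc$src, mode = fc$mode),
    wavelet = wav)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null", dataframe = "rows")
  pipe_log(con, "pipeline complete; summary.json written")
  invisible(summary)
}
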