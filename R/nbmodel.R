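#' Specify a lagged negative-binomial count model
#'
#' A model specification is a set of lagged meteorological main effects, an
#' optional set of pairwise interactions between them, and an optional
#' autoregressive term (the per-trap abundance of the previous week). The
#' linear predictor never contains an intercept, and the offset is always
#' `log(observed_traps)`. To limit collinearity at most one temperature and
#' one humidity main effect may be included.
#'
#' @param terms list of `c(variable, lag)` pairs (or a 2-column data.frame
#'   `variable`, `lag`); variables are `"precip"`, `"tmin"`, `"tavg"`,
#'   `"tmax"`, `"hmin"`, `"havg"`, `"hmax"`, `"wind"`; lags `0..4`.
#' @param interactions list of character pairs of variables already present
#'   in `terms`; each contributes the elementwise product of the two lagged
#'   columns.
#' @param ar include the AR(1) per-trap abundance term (lag fixed at 1)?
#' @return an object of class `nb_model_spec`.
#' @examples
#' nb_model_spec(list(c("tmin", 4), c("hmin", 2)),
#'               interactions = list(c("tmin", "hmin")), ar = TRUE)
#' @export
nb_model_spec <- function(terms = list(), interactions = list(), ar = TRUE) {
  if (is.data.frame(terms)) {
    terms <- lapply(seq_len(nrow(terms)),
                    function(i) c(terms$variable[i], terms$lag[i]))
  }
  tl <- lapply(terms, function(tm) {
    v <- as.character(tm[1]); l <- as.integer(tm[2])
    if (!v %in% names(meteo_vars)) stop("unknown variable '", v, "'")
    if (is.na(l) || l < 0 || l > 4) stop("lag must be in 0..4 for '", v, "'")
    list(variable = v, lag = l)
  })
  vars <- vapply(tl, `[[`, "", "variable")
  if (anyDuplicated(vars)) stop("duplicated main-effect variable")
  if (sum(vars %in% c("tmin", "tavg", "tmax")) > 1 ||
      sum(vars %in% c("hmin", "havg", "hmax")) > 1) {
    stop("at most one temperature and one humidity main effect allowed")
  }
  for (ia in interactions) {
    if (length(ia) != 2 || !all(ia %in% vars)) {
      stop("interactions must pair two included main-effect variables")
    }
  }
  structure(list(terms = tl, interactions = interactions, ar = isTRUE(ar)),
            class = "nb_model_spec")
}

term_colname <- function(v, l) paste0(v, "_l", l)

#' Build the design matrix, response and offset for a model specification
#'
#' Lags every main effect, forms interaction columns as elementwise products
#' of the (already lagged) main-effect columns, adds the AR(1) per-trap
#' abundance column, and drops the leading rows where any lag is
#' unavailable. There is no intercept column; the offset is
#' `log(observed_traps)`.
#'
#' @param d an `aedes_dataset`.
#' @param spec an [nb_model_spec()].
#' @param align_lag optional integer: treat this many leading rows as
#'   unavailable regardless of the spec's own lags, so that models with
#'   different lag structures can be fitted on an identical sample (required
#'   for AIC comparability in [select_model()]).
#' @return a list of class `nb_design`: `X` (matrix), `y`, `offset`,
#'   `rows_used` (indices into `d`), `roles` (which column is the
#'   temperature, humidity, interaction and AR term).
#' @export
build_design <- function(d, spec, align_lag = NULL) {
  stopifnot(inherits(d, "aedes_dataset"), inherits(spec, "nb_model_spec"))
  cols <- list()
  roles <- list(temp = NULL, hum = NULL, inter = NULL, ar = NULL)
  for (tm in spec$terms) {
    nm <- term_colname(tm$variable, tm$lag)
    cols[[nm]] <- lagged(d[[meteo_vars[[tm$variable]]]], tm$lag)
    if (tm$variable %in% c("tmin", "tavg", "tmax")) roles$temp <- nm
    if (tm$variable %in% c("hmin", "havg", "hmax")) roles$hum <- nm
  }
  for (ia in spec$interactions) {
    n1 <- term_colname(ia[1], spec$terms[[match(ia[1], vapply(spec$terms, `[[`, "", "variable"))]]$lag)
    n2 <- term_colname(ia[2], spec$terms[[match(ia[2], vapply(spec$terms, `[[`, "", "variable"))]]$lag)
    nm <- paste0(n1, "_x_", n2)
    cols[[nm]] <- cols[[n1]] * cols[[n2]]
    roles$inter <- nm
  }
  if (spec$ar) {
    cols[["ar1"]] <- lagged(d$abundance, 1)
    roles$ar <- "ar1"
  }
  if (!length(cols)) stop("empty model specification")
  X <- do.call(cbind, cols)
  keep <- stats::complete.cases(X)
  if (!is.null(align_lag)) keep[seq_len(min(align_lag, nrow(d)))] <- FALSE
  rows <- which(keep)
  if (length(rows) < ncol(X) + 2) stop("too few usable rows for this spec")
  structure(list(X = X[rows, , drop = FALSE],
                 y = d$total_captures[rows],
                 offset = log(d$observed_traps[rows]),
                 rows_used = rows, roles = roles, spec = spec,
                 weeks = d$week[rows]),
            class = "nb_design")
}

nb_loglik <- function(beta, theta, X, y, off) {
  mu <- exp(drop(X %*% beta) + off)
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

#' Fit the negative-binomial count model
#'
#' Jointly maximizes the negative-binomial log-likelihood over the
#' coefficients and the overdispersion parameter theta by alternating IRLS
#' and theta profiling (via [MASS::glm.nb()]); with `theta` supplied, fits a
#' fixed-theta NB GLM instead. Standard errors come from the observed
#' information and p-values are two-sided Wald tests. The reported AIC counts
#' theta as a parameter: `AIC = -2 loglik + 2 (n_coef + 1)`.
#'
#' @param design an [build_design()] result.
#' @param theta optional fixed overdispersion; `NULL` (default) estimates it.
#' @param maxit IRLS iteration cap; non-convergence is an error carrying the
#'   trace of theta iterations.
#' @return an object of class `nbfit`: `coefficients` (a data.frame with
#'   `estimate`, `se`, `z`, `p`), `theta`, `se_theta`, `loglik`, `aic`,
#'   `deviance`, `fitted`, `residuals_deviance`, `residuals_pearson`,
#'   `vcov`, `rows_used`, `roles`, `converged`.
#' @export
fit_nb <- function(design, theta = NULL, maxit = 100) {
  stopifnot(inherits(design, "nb_design"))
  dat <- as.data.frame(design$X)
  dat$.y <- design$y
  dat$.off <- design$offset
  rhs <- paste(c("0", sprintf("`%s`", colnames(design$X)), "offset(.off)"),
               collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  if (is.null(theta)) {
    fit <- withCallingHandlers(
      MASS::glm.nb(fml, data = dat,
                   control = stats::glm.control(maxit = maxit)),
      warning = function(w) {
        if (grepl("iteration limit reached", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (!fit$converged) {
      stop("negative-binomial fit did not converge after ", maxit,
           " iterations (theta trace: ",
           paste(signif(fit$th.trace, 5), collapse = " -> "), ")")
    }
    th <- fit$theta
    se_th <- fit$SE.theta
    npar <- length(stats::coef(fit)) + 1
  } else {
    stopifnot(theta > 0)
    fit <- stats::glm(fml, data = dat,
                      family = MASS::negative.binomial(theta),
                      control = stats::glm.control(maxit = maxit))
    if (!fit$converged) stop("fixed-theta NB fit did not converge")
    th <- theta
    se_th <- NA_real_
    npar <- length(stats::coef(fit))
  }
  est <- stats::coef(fit)
  if (any(!is.finite(est))) stop("separation/overflow: non-finite estimates")
  V <- stats::summary.glm(fit, dispersion = 1)$cov.scaled
  se <- sqrt(diag(V))
  z <- est / se
  ll <- nb_loglik(est, th, design$X, design$y, design$offset)
  cf <- data.frame(term = colnames(design$X), estimate = unname(est),
                   se = unname(se), z = unname(z),
                   p = unname(2 * stats::pnorm(-abs(z))),
                   stringsAsFactors = FALSE)
  mu <- unname(fit$fitted.values)
  structure(list(coefficients = cf, theta = th, se_theta = se_th,
                 loglik = ll, aic = -2 * ll + 2 * npar,
                 deviance = fit$deviance,
                 fitted = mu,
                 residuals_deviance = unname(stats::residuals(fit, "deviance")),
                 residuals_pearson = unname(stats::residuals(fit, "pearson")),
                 vcov = V, rows_used = design$rows_used,
                 roles = design$roles, spec = design$spec,
                 weeks = design$weeks, converged = TRUE,
                 theta_fixed = !is.null(theta)),
            class = "nbfit")
}

#' @export
print.nbfit <- function(x, ...) {
  cat("Negative-binomial count model (no intercept, offset log(traps))\n")
  print(x$coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("theta = %.4f   logLik = %.2f   AIC = %.2f   deviance = %.2f\n",
              x$theta, x$loglik, x$aic, x$deviance))
  invisible(x)
}

#' Univariate lag screening
#'
#' Fits each candidate (variable, lag) pair as the sole covariate of the
#' count model (offset, no intercept) and retains the pairs whose Wald
#' p-value is below `alpha`, ranked by increasing p (ties broken by smaller
#' lag, then variable name). The AR(1) term may be screened alongside by
#' including `"ar"` among the variables (its lag is fixed at 1). Per
#' variable, the single best lag (attribute `"best_per_variable"`) is what
#' model selection carries forward.
#'
#' @param d an `aedes_dataset`.
#' @param variables character vector of variables to screen.
#' @param lags integer lags to try (subset of `0..4`).
#' @param alpha significance level of the screen.
#' @return a data.frame of class `screen_table` (columns `variable`, `lag`,
#'   `estimate`, `se`, `p`) with the significant pairs in rank order;
#'   attributes `all_fits` (every attempted cell, including failures) and
#'   `best_per_variable`.
#' @export
univariate_screen <- function(d, variables = c(names(meteo_vars), "ar"),
                              lags = 0:4, alpha = 0.05) {
  stopifnot(inherits(d, "aedes_dataset"), alpha > 0, alpha < 1,
            all(lags %in% 0:4))
  rows <- list()
  for (v in variables) {
    vlags <- if (v == "ar") 1L else lags
    for (l in vlags) {
      spec <- if (v == "ar") nb_model_spec(ar = TRUE)
              else nb_model_spec(list(c(v, l)), ar = FALSE)
      res <- tryCatch({
        f <- fit_nb(build_design(d, spec))
        cf <- f$coefficients[1, ]
        data.frame(variable = v, lag = l, estimate = cf$estimate,
                   se = cf$se, p = cf$p, error = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(variable = v, lag = l, estimate = NA_real_, se = NA_real_,
                   p = NA_real_, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  all_fits <- do.call(rbind, rows)
  ok <- all_fits[!is.na(all_fits$p), ]
  ok <- ok[order(ok$p, ok$lag, ok$variable), ]
  sig <- ok[ok$p < alpha, c("variable", "lag", "estimate", "se", "p")]
  rownames(sig) <- NULL
  best <- sig[!duplicated(sig$variable), ]
  rownames(best) <- NULL
  structure(sig, class = c("screen_table", "data.frame"),
            all_fits = all_fits, best_per_variable = best, alpha = alpha)
}

#' AIC selection over temperature-by-humidity interaction models
#'
#' For every screened temperature variable paired with every screened
#' humidity variable (each at its best screened lag), fits the model with
#' the two main effects, their interaction and the AR(1) term, and returns
#' the minimum-AIC fit together with the full candidate ranking. With all
#' three temperature and all three humidity summaries screened in, this is
#' the nine-combination comparison. All candidates are fitted on an
#' identical sample (rows dropped up to the largest lag over all candidates)
#' so their AICs are comparable.
#'
#' @param d an `aedes_dataset`.
#' @param screened a `screen_table` from [univariate_screen()] containing at
#'   least one temperature and one humidity variable.
#' @return a list of class `nb_selection`: `best` (an `nbfit`), `ranking`
#'   (data.frame sorted by AIC), `fits` (all successful fits, in ranking
#'   order).
#' @export
select_model <- function(d, screened) {
  stopifnot(inherits(d, "aedes_dataset"), inherits(screened, "screen_table"))
  best <- attr(screened, "best_per_variable")
  tv <- best[best$variable %in% c("tmin", "tavg", "tmax"), ]
  hv <- best[best$variable %in% c("hmin", "havg", "hmax"), ]
  if (nrow(tv) == 0 || nrow(hv) == 0) {
    stop("screening must retain at least one temperature and one humidity ",
         "variable")
  }
  max_lag <- max(c(tv$lag, hv$lag, 1L))
  cand <- expand.grid(ti = seq_len(nrow(tv)), hi = seq_len(nrow(hv)))
  fits <- list()
  rk <- list()
  for (i in seq_len(nrow(cand))) {
    tt <- tv[cand$ti[i], ]
    hh <- hv[cand$hi[i], ]
    spec <- nb_model_spec(list(c(tt$variable, tt$lag), c(hh$variable, hh$lag)),
                          interactions = list(c(tt$variable, hh$variable)),
                          ar = TRUE)
    res <- tryCatch(fit_nb(build_design(d, spec, align_lag = max_lag)),
                    error = function(e) e)
    rk[[i]] <- data.frame(temp_var = tt$variable, temp_lag = tt$lag,
                          hum_var = hh$variable, hum_lag = hh$lag,
                          aic = if (inherits(res, "error")) NA_real_ else res$aic,
                          deviance = if (inherits(res, "error")) NA_real_ else res$deviance,
                          error = if (inherits(res, "error"))
                            conditionMessage(res) else NA_character_,
                          stringsAsFactors = FALSE)
    if (!inherits(res, "error")) fits[[i]] <- res
  }
  ranking <- do.call(rbind, rk)
  ok <- which(!is.na(ranking$aic))
  if (!length(ok)) stop("all candidate models failed to fit")
  ord <- ok[order(ranking$aic[ok])]
  ranking <- ranking[c(ord, setdiff(seq_len(nrow(ranking)), ok)), ]
  rownames(ranking) <- NULL
  structure(list(best = fits[[ord[1]]], ranking = ranking,
                 fits = fits[ord]),
            class = "nb_selection")
}

#' Autocorrelation and partial autocorrelation with white-noise bands
#'
#' @param x numeric series (non-constant).
#' @param max_lag largest lag, `< length(x)`.
#' @return list with `acf` (lags `0..max_lag`, `acf[1] == 1`), `pacf` (lags
#'   `1..max_lag`, Durbin-Levinson), `band` (`1.96/sqrt(n)`), `n`.
#' @export
acf_pacf <- function(x, max_lag = 20) {
  stopifnot(length(x) > max_lag, max_lag >= 1)
  if (stats::sd(x) == 0) stop("autocorrelation undefined for constant series")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)
  p <- stats::pacf(x, lag.max = max_lag, plot = FALSE)
  list(acf = drop(a$acf), pacf = drop(p$acf),
       band = stats::qnorm(0.975) / sqrt(length(x)), n = length(x))
}

#' Out-of-fit forecast of weekly captures
#'
#' Predicts the expected captures for `horizon` weeks past `origin` using
#' the covariates of `d`. In `"one_step"` mode the AR(1) term uses the
#' observed per-trap abundance of the previous week (forecast evaluated
#' against the realized series week by week); in `"iterated"` mode the
#' predicted abundance is propagated. 95% intervals combine coefficient
#' uncertainty (delta method on the linear predictor; theta uncertainty is
#' ignored) with negative-binomial quantiles. The Spearman rank correlation
#' against the observed counts (average ranks for ties) scores the forecast.
#'
#' @param fit an `nbfit`.
#' @param d the `aedes_dataset` extending at least `origin + horizon` weeks,
#'   with meteorology available throughout.
#' @param origin index of the last fitted week.
#' @param horizon number of weeks ahead (>= 1).
#' @param mode `"one_step"` (default) or `"iterated"`.
#' @param level interval coverage.
#' @return a list of class `nb_forecast`: `pred` (data.frame `week`, `mu`,
#'   `lwr`, `upr`, `observed`), `src` (Spearman coefficient), `mode`.
#' @export
forecast_nb <- function(fit, d, origin, horizon,
                        mode = c("one_step", "iterated"), level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "nbfit"), inherits(d, "aedes_dataset"),
            horizon >= 1, origin >= 1)
  if (origin + horizon > nrow(d)) {
    stop("dataset ends before origin + horizon (missing future meteorology)")
  }
  spec <- fit$spec
  beta <- fit$coefficients$estimate
  names(beta) <- fit$coefficients$term
  zq <- stats::qnorm(1 - (1 - level) / 2)
  mu <- lwr <- upr <- numeric(horizon)
  a_prev <- d$abundance[origin]
  for (h in seq_len(horizon)) {
    t <- origin + h
    x <- numeric(length(beta))
    names(x) <- names(beta)
    vals <- list()
    for (tm in spec$terms) {
      nm <- term_colname(tm$variable, tm$lag)
      vals[[nm]] <- d[[meteo_vars[[tm$variable]]]][t - tm$lag]
      x[nm] <- vals[[nm]]
    }
    for (ia in spec$interactions) {
      lag1 <- spec$terms[[match(ia[1], vapply(spec$terms, `[[`, "", "variable"))]]$lag
      lag2 <- spec$terms[[match(ia[2], vapply(spec$terms, `[[`, "", "variable"))]]$lag
      nm <- paste0(term_colname(ia[1], lag1), "_x_", term_colname(ia[2], lag2))
      x[nm] <- vals[[term_colname(ia[1], lag1)]] * vals[[term_colname(ia[2], lag2)]]
    }
    if (spec$ar) {
      x["ar1"] <- if (mode == "one_step") d$abundance[t - 1] else a_prev
    }
    eta <- sum(x * beta)
    se_eta <- sqrt(drop(t(x) %*% fit$vcov %*% x))
    N <- d$observed_traps[t]
    mu[h] <- N * exp(eta)
    lwr[h] <- stats::qnbinom((1 - level) / 2, size = fit$theta,
                             mu = N * exp(eta - zq * se_eta))
    upr[h] <- stats::qnbinom(1 - (1 - level) / 2, size = fit$theta,
                             mu = N * exp(eta + zq * se_eta))
    if (mode == "iterated") a_prev <- mu[h] / d$positive_traps[t]
  }
  idx <- origin + seq_len(horizon)
  obs <- d$total_captures[idx]
  src <- spearman_rank(mu, obs)
  structure(list(pred = data.frame(week = d$week[idx], mu = mu, lwr = lwr,
                                   upr = upr, observed = obs,
                                   stringsAsFactors = FALSE),
                 src = src, mode = mode, level = level),
            class = "nb_forecast")
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  stats::cor(x, y, method = "spearman")
}
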