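# Small in-code fixtures and independent oracles shared across tests.

# minimal valid entomological table
make_entomo <- function(n = 8, start = "2010-W01", captures = NULL,
                        positive = NULL, observed = NULL) {
  if (is.null(captures)) captures <- 100 + seq_len(n)
  if (is.null(positive)) positive <- rep(50L, n)
  if (is.null(observed)) observed <- rep(60L, n)
  entomo_series(week_seq(start, n), captures, positive, observed)
}

# minimal valid meteorological table (constant climate)
make_meteo <- function(n = 8, start = "2010-W01", precip = NULL) {
  if (is.null(precip)) precip <- rep(10, n)
  meteo_series(week_seq(start, n), precip,
               tmin_c = rep(19, n), tavg_c = rep(24, n), tmax_c = rep(30, n),
               hmin_pct = rep(56, n), havg_pct = rep(76, n),
               hmax_pct = rep(91, n), wind_ms = rep(2.9, n))
}

# null surveillance dataset: per-trap mean exactly 1 (mu = observed traps),
# climate generated independently of the counts
null_dataset <- function(n = 90, theta = 19.11, seed = 1) {
  set.seed(seed)
  N <- rep(425L, n)
  y <- rnbinom(n, size = theta, mu = N)
  cl <- climate_params()
  cl$seed <- seed + 500000L
  m <- generate_climate(cl, n)
  e <- entomo_series(m$week, y, pmax(1L, pmin(N, y)), N)
  align_weekly(e, m)
}

# direct (non-FFT) time-domain Morlet convolution, one scale
direct_cwt_scale <- function(x, s, dt = 1, omega0 = 6) {
  n <- length(x)
  xm <- x - mean(x)
  W <- complex(n)
  for (t in 1:n) {
    u <- (1:n - t) * dt / s
    psi <- pi^(-1 / 4) * sqrt(dt / s) * exp(1i * omega0 * u - u^2 / 2)
    W[t] <- sum(xm * Conj(psi))
  }
  W
}

# independent NB log-likelihood (direct parameterization, no link machinery)
nb_loglik_direct <- function(par, X, y, off) {
  beta <- par[-length(par)]
  theta <- exp(par[length(par)])
  mu <- exp(drop(X %*% beta) + off)
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu)))
}

# analytic score of nb_loglik_direct (beta..., log theta)
nb_score_direct <- function(par, X, y, off) {
  beta <- par[-length(par)]
  theta <- exp(par[length(par)])
  mu <- exp(drop(X %*% beta) + off)
  gb <- drop(t(X) %*% ((y - mu) * theta / (theta + mu)))
  gt <- sum(digamma(y + theta) - digamma(theta) +
              log(theta / (theta + mu)) + 1 - (theta + y) / (theta + mu))
  c(gb, gt * theta)
}
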