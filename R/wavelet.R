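# Morlet continuous wavelet transform and red-noise significance.
#
# Conventions: Morlet mother wavelet with nondimensional frequency
# omega0 = 6; scales s_j = s0 * 2^(j*dj); Fourier period
# lambda = 4*pi*s / (omega0 + sqrt(2 + omega0^2)); FFT-based convolution on
# the zero-padded series with the energy normalization sqrt(2*pi*s/dt) that
# makes the expected power of white noise flat across scales; cone of
# influence from the e-folding distance sqrt(2)*s of the wavelet envelope.

morlet_fourier_factor <- function(omega0 = 6) {
  4 * pi / (omega0 + sqrt(2 + omega0^2))
}

#' Standardize (and optionally log-transform) a series for spectral analysis
#'
#' Applies the natural log (after adding `zero_offset`, useful for series
#' with exact zeros such as precipitation) and standardizes to zero mean and
#' unit standard deviation. The log step brings skewed positive series
#' closer to normality, which improves the accuracy of the chi-squared
#' significance test; standardization makes spectra comparable across
#' variables (scale changes of the input do not change the spectrum).
#'
#' @param x numeric series, length >= 16.
#' @param zero_offset constant added before the log.
#' @param log apply the log step? Set `FALSE` for series with non-positive
#'   values whose scale is already meaningful (e.g. test sinusoids).
#' @return standardized numeric series (mean 0, sd 1).
#' @export
preprocess <- function(x, zero_offset = 0, log = TRUE) {
  stopifnot(length(x) >= 16)
  if (log) {
    z <- x + zero_offset
    if (any(z <= 0)) {
      stop("non-positive value at index ", which(z <= 0)[1],
           " after adding zero_offset; increase zero_offset")
    }
    x <- base::log(z)
  }
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a constant series")
  (x - mean(x)) / s
}

#' Morlet continuous wavelet transform
#'
#' FFT-based CWT with zero-padding to the next power of two (doubling when
#' the length already is one, so padding is never empty). Padding is removed
#' before returning; the cone of influence is computed on the unpadded axis
#' and is zero at both edges.
#'
#' @param x numeric series (typically [preprocess()]ed).
#' @param dt sampling interval (weeks).
#' @param dj scale resolution (octaves are split into `1/dj` scales).
#' @param s0 smallest scale.
#' @param J index of the largest scale (`scales = s0*2^((0:J)*dj)`);
#'   `NULL` uses `floor(log2(n*dt/s0)/dj)`.
#' @param omega0 Morlet nondimensional frequency.
#' @return an object of class `aedes_cwt`: complex matrix `W`
#'   (`J+1` scales x `n` times), `power = |W|^2`, `scale`, `period`
#'   (Fourier periods), `coi` (maximum edge-unaffected period per time),
#'   `in_coi` (logical matrix), `dt`, `dj`, `omega0`, `n`, `series`,
#'   `series_var`.
#' @examples
#' x <- preprocess(sin(2 * pi * (1:128) / 8), log = FALSE)
#' cw <- cwt_morlet(x)
#' cw$period[which.max(rowMeans(cw$power))]
#' @export
cwt_morlet <- function(x, dt = 1, dj = 1 / 12, s0 = 2 * dt, J = NULL,
                       omega0 = 6) {
  n <- length(x)
  if (n * dt < 2 * s0) stop("series shorter than twice the smallest scale")
  if (is.null(J)) J <- floor(log2(n * dt / s0) / dj)
  stopifnot(J >= 1, dj > 0, s0 > 0)
  scales <- s0 * 2^((0:J) * dj)

  npad <- 2^ceiling(log2(n))
  if (npad == n) npad <- 2L * n
  xpad <- c(x - mean(x), rep(0, npad - n))
  fx <- stats::fft(xpad)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))

  W <- matrix(0i, nrow = J + 1, ncol = n)
  norm0 <- pi^(-1 / 4)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- norm0 * sqrt(2 * pi * s / dt) *
      exp(-(s * omega - omega0)^2 / 2) * (omega > 0)
    W[j, ] <- stats::fft(fx * psi_hat, inverse = TRUE)[1:n] / npad
  }

  ff <- morlet_fourier_factor(omega0)
  period <- ff * scales
  dist_edge <- pmin(0:(n - 1), (n - 1):0) * dt
  coi <- ff / sqrt(2) * dist_edge
  in_coi <- outer(period, coi, `<=`)

  structure(list(W = W, power = Mod(W)^2, scale = scales, period = period,
                 coi = coi, in_coi = in_coi, dt = dt, dj = dj,
                 omega0 = omega0, n = n, series = x,
                 series_var = stats::var(x)),
            class = "aedes_cwt")
}

#' Red-noise significance of a wavelet power spectrum
#'
#' Tests each time-scale cell of the power spectrum against the theoretical
#' spectrum of a first-order autoregressive (red-noise) null with the lag-1
#' autocorrelation estimated from the series itself:
#' `P(lambda) = (1 - r1^2) / (1 + r1^2 - 2*r1*cos(2*pi*dt/lambda))`,
#' scaled by the series variance. Since the Morlet transform is complex,
#' the power of a Gaussian red-noise process at each cell is distributed as
#' `P * chi^2_2 / 2`, giving the pointwise threshold
#' `var * P * qchisq(level, 2) / 2`.
#'
#' @param cwt an [cwt_morlet()] result.
#' @param x the series the transform came from (default: the stored one).
#' @param level confidence level of the contour.
#' @return list of class `significance_mask`: `mask` (logical matrix, `TRUE`
#'   where power exceeds the threshold), `threshold` (per scale), `r1`,
#'   `background` (per-scale null spectrum), `level`.
#' @export
red_noise_significance <- function(cwt, x = cwt$series, level = 0.95) {
  stopifnot(inherits(cwt, "aedes_cwt"), level > 0, level < 1)
  r1 <- lag1_autocor(x)
  if (!is.finite(r1) || abs(r1) >= 1) {
    stop("degenerate lag-1 autocorrelation (|r1| >= 1 or undefined)")
  }
  freq <- cwt$dt / cwt$period
  bg <- (1 - r1^2) / (1 + r1^2 - 2 * r1 * cos(2 * pi * freq))
  threshold <- stats::var(x) * bg * stats::qchisq(level, df = 2) / 2
  mask <- sweep(cwt$power, 1, threshold, `>`)
  structure(list(mask = mask, threshold = threshold, r1 = r1,
                 background = bg, level = level),
            class = "significance_mask")
}

lag1_autocor <- function(x) {
  if (stats::sd(x) == 0) return(NA_real_)
  drop(stats::acf(x, lag.max = 1, plot = FALSE)$acf[2])
}

#' Cross-wavelet spectrum of two transforms
#'
#' `W_xy = W_x * Conj(W_y)` on a shared time/scale grid. The relative phase
#' is reported in degrees with the arrow convention of the coherence
#' literature (anti-clockwise from east): 0 means the series are in phase;
#' +90 means the second series is a quarter period ahead of the first; 180
#' (or -180) means anti-phase; -90 means a quarter period behind.
#'
#' @param cx,cy [cwt_morlet()] results on identical axes (same `n`, scales
#'   and `dt`).
#' @return list of class `aedes_xwt`: `Wxy`, `power = |Wxy|`,
#'   `phase_deg` in `(-180, 180]`, plus the shared `scale`, `period`,
#'   `coi`, `in_coi`, `dt`.
#' @export
cross_wavelet <- function(cx, cy) {
  stopifnot(inherits(cx, "aedes_cwt"), inherits(cy, "aedes_cwt"))
  if (cx$n != cy$n || cx$dt != cy$dt ||
      length(cx$scale) != length(cy$scale) ||
      any(abs(cx$scale - cy$scale) > 1e-12)) {
    stop("mismatched time or scale axes between the two transforms")
  }
  Wxy <- cx$W * Conj(cy$W)
  phase <- Arg(cy$W * Conj(cx$W)) * 180 / pi  # + = second series ahead
  phase[phase <= -180] <- phase[phase <= -180] + 360
  structure(list(Wxy = Wxy, power = Mod(Wxy), phase_deg = phase,
                 scale = cx$scale, period = cx$period, coi = cx$coi,
                 in_coi = cx$in_coi, dt = cx$dt, dj = cx$dj, n = cx$n,
                 omega0 = cx$omega0),
            class = "aedes_xwt")
}

#' Interaction series for spectral analysis
#'
#' The joint forcing of two interacting meteorological variables is analyzed
#' spectrally as the elementwise product of the two raw series, then
#' preprocessed like any other series.
#'
#' @param a,b numeric series on the same week axis.
#' @param zero_offset passed to [preprocess()].
#' @param log passed to [preprocess()].
#' @return standardized product series.
#' @export
interaction_series <- function(a, b, zero_offset = 0, log = TRUE) {
  stopifnot(length(a) == length(b))
  preprocess(a * b, zero_offset = zero_offset, log = log)
}

#' Long-format serialization of a spectrum
#'
#' @param obj an `aedes_cwt`, `aedes_xwt` or `aedes_wtc`.
#' @param path CSV output path.
#' @param mask optional `significance_mask` (for `aedes_cwt`).
#' @param weeks optional week labels for the time axis.
#' @return the path, invisibly. Columns: `time`, `week` (if given), `scale`,
#'   `period`, `value`, `phase_deg` (cross-spectra), `significant`,
#'   `in_coi`.
#' @export
write_spectrum_csv <- function(obj, path, mask = NULL, weeks = NULL) {
  val <- if (inherits(obj, "aedes_wtc")) obj$R2
         else if (inherits(obj, "aedes_xwt")) obj$power
         else obj$power
  nsc <- nrow(val); nt <- ncol(val)
  out <- data.frame(time = rep(seq_len(nt), each = nsc),
                    scale = rep(obj$scale, nt),
                    period = rep(obj$period, nt),
                    value = as.vector(val))
  if (!is.null(weeks)) out$week <- rep(weeks, each = nsc)
  if (inherits(obj, "aedes_xwt")) out$phase_deg <- as.vector(obj$phase_deg)
  sig <- if (!is.null(mask)) mask$mask else obj$mask
  if (!is.null(sig)) out$significant <- as.vector(sig)
  out$in_coi <- as.vector(obj$in_coi)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a wavelet power spectrum
#'
#' Time-period image (log2 period axis), significance contour and cone of
#' influence, in the layout usual for wavelet spectra.
#'
#' @param x an `aedes_cwt` or `aedes_xwt`.
#' @param mask optional `significance_mask`.
#' @param main title.
#' @param ... ignored.
#' @export
plot.aedes_cwt <- function(x, mask = NULL, main = "Wavelet power spectrum",
                           ...) {
  pw <- if (inherits(x, "aedes_xwt")) x$power else x$power
  tt <- seq_len(x$n) * x$dt
  lp <- log2(x$period)
  graphics::image(tt, lp, t(pw), col = grDevices::hcl.colors(64, "Spectral",
                                                             rev = TRUE),
                  xlab = "time (weeks)", ylab = "period (weeks, log2)",
                  yaxt = "n", main = main)
  at <- pretty(lp)
  graphics::axis(2, at = at, labels = signif(2^at, 3))
  if (!is.null(mask)) {
    graphics::contour(tt, lp, t(mask$mask * 1), levels = 0.5, add = TRUE,
                      drawlabels = FALSE, lwd = 2)
  }
  coi <- pmax(x$coi, min(x$period))
  graphics::lines(tt, log2(coi), lwd = 2)
  invisible(x)
}

#' @export
plot.aedes_xwt <- function(x, ...) plot.aedes_cwt(x, ...,
                                                  main = "Cross-wavelet power")
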