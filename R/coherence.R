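# Smoothed wavelet coherence with Monte-Carlo surrogate significance.
#
# R2(s,t) = |S(W_xy / s)|^2 / ( S(|W_x|^2 / s) * S(|W_y|^2 / s) )
# with the smoothing operator S acting in time (Gaussian of sd = s/dt
# samples per scale, applied in the frequency domain) and in scale (boxcar
# of 0.6/dj scales). Because the same positive-kernel operator smooths the
# numerator and the denominator, Cauchy-Schwarz bounds R2 in [0,1] and the
# coherence of a series with itself is exactly 1 at every point.

# Gaussian time smoothing of each scale row, frequency-domain implementation
smooth_time <- function(M, scale, dt, n) {
  L <- 2^ceiling(log2(2 * n))
  nsc <- nrow(M)
  P <- matrix(0i, nrow = L, ncol = nsc)
  P[1:n, ] <- t(M)
  F <- stats::mvfft(P)
  k <- 0:(L - 1)
  om <- ifelse(k <= L / 2, 2 * pi * k / L, -2 * pi * (L - k) / L)
  for (j in seq_len(nsc)) {
    F[, j] <- F[, j] * exp(-0.5 * (scale[j] / dt * om)^2)
  }
  out <- stats::mvfft(F, inverse = TRUE)[1:n, , drop = FALSE] / L
  t(out)
}

# boxcar smoothing across scales, width 0.6/dj scales, edge-renormalized
smooth_scale <- function(M, dj, width = 0.6) {
  hw <- max(0L, round(width / dj / 2))
  if (hw == 0L) return(M)
  nsc <- nrow(M)
  out <- M
  for (j in seq_len(nsc)) {
    idx <- max(1L, j - hw):min(nsc, j + hw)
    out[j, ] <- colMeans(M[idx, , drop = FALSE])
  }
  out
}

wtc_smooth <- function(M, scale, dt, dj, n) {
  smooth_scale(smooth_time(M, scale, dt, n), dj)
}

coherence_r2 <- function(cx, cy) {
  sinv <- 1 / cx$scale
  num <- wtc_smooth(sweep(cx$W * Conj(cy$W), 1, sinv, `*`),
                    cx$scale, cx$dt, cx$dj, cx$n)
  sx <- Re(wtc_smooth(sweep(Mod(cx$W)^2, 1, sinv, `*`),
                      cx$scale, cx$dt, cx$dj, cx$n))
  sy <- Re(wtc_smooth(sweep(Mod(cy$W)^2, 1, sinv, `*`),
                      cy$scale, cy$dt, cy$dj, cy$n))
  R2 <- Mod(num)^2 / pmax(sx * sy, .Machine$double.xmin)
  pmin(pmax(R2, 0), 1)
}

ar1_surrogate <- function(n, phi) {
  ar1_noise(n, phi, sd = 1)
}

#' Wavelet coherence of two series
#'
#' Computes the smoothed wavelet coherence of the two transforms and, when
#' `n_surrogates > 0`, a Monte-Carlo significance mask: pairs of independent
#' AR(1) surrogates matched to each input's lag-1 autocorrelation are run
#' through the same coherence computation, their in-COI values pooled per
#' scale, and the observed coherence compared with the `level` quantile.
#' The smallest scale must keep a time-smoothing window of at least one
#' sample (`scale/dt >= 1`), otherwise the smoothing is degenerate and an
#' error is raised.
#'
#' @param cx,cy [cwt_morlet()] results on identical axes.
#' @param n_surrogates number of surrogate pairs (0 skips significance).
#' @param level significance level of the mask.
#' @param seed optional seed for the surrogate draws.
#' @return list of class `aedes_wtc`: `R2` (coherence in `[0,1]`), `mask`
#'   (logical, `NULL` if no surrogates), `threshold` (per scale), `r1`
#'   (estimated lag-1 autocorrelations of the two inputs), `n_surrogates`,
#'   `level`, plus shared axes (`scale`, `period`, `coi`, `in_coi`).
#' @export
coherence <- function(cx, cy, n_surrogates = 300, level = 0.95, seed = NULL) {
  stopifnot(inherits(cx, "aedes_cwt"), inherits(cy, "aedes_cwt"))
  if (cx$n != cy$n || length(cx$scale) != length(cy$scale) ||
      any(abs(cx$scale - cy$scale) > 1e-12)) {
    stop("mismatched time or scale axes between the two transforms")
  }
  if (min(cx$scale) / cx$dt < 1) {
    stop("degenerate smoothing: smallest scale is under one sample")
  }
  R2 <- coherence_r2(cx, cy)
  mask <- NULL
  threshold <- NULL
  r1x <- lag1_autocor(cx$series)
  r1y <- lag1_autocor(cy$series)
  if (n_surrogates > 0) {
    nsc <- length(cx$scale)
    J <- nsc - 1
    surr <- vector("list", n_surrogates)
    with_seed(seed, {
      for (i in seq_len(n_surrogates)) {
        sx <- cwt_morlet(ar1_surrogate(cx$n, r1x), dt = cx$dt, dj = cx$dj,
                         s0 = min(cx$scale), J = J, omega0 = cx$omega0)
        sy <- cwt_morlet(ar1_surrogate(cy$n, r1y), dt = cx$dt, dj = cx$dj,
                         s0 = min(cx$scale), J = J, omega0 = cx$omega0)
        surr[[i]] <- coherence_r2(sx, sy)
      }
    })
    threshold <- vapply(seq_len(nsc), function(j) {
      inc <- cx$in_coi[j, ]
      if (!any(inc)) return(Inf)
      v <- unlist(lapply(surr, function(m) m[j, inc]), use.names = FALSE)
      if (length(v) < 20) Inf else stats::quantile(v, level, names = FALSE)
    }, 0)
    mask <- sweep(R2, 1, threshold, `>`)
  }
  structure(list(R2 = R2, mask = mask, threshold = threshold,
                 r1 = c(x = r1x, y = r1y), n_surrogates = n_surrogates,
                 level = level, scale = cx$scale, period = cx$period,
                 coi = cx$coi, in_coi = cx$in_coi, dt = cx$dt, dj = cx$dj,
                 n = cx$n),
            class = "aedes_wtc")
}

#' @export
plot.aedes_wtc <- function(x, ...) {
  tt <- seq_len(x$n) * x$dt
  lp <- log2(x$period)
  graphics::image(tt, lp, t(x$R2), zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  xlab = "time (weeks)", ylab = "period (weeks, log2)",
                  yaxt = "n", main = "Wavelet coherence")
  at <- pretty(lp)
  graphics::axis(2, at = at, labels = signif(2^at, 3))
  if (!is.null(x$mask)) {
    graphics::contour(tt, lp, t(x$mask * 1), levels = 0.5, add = TRUE,
                      drawlabels = FALSE, lwd = 2)
  }
  graphics::lines(tt, log2(pmax(x$coi, min(x$period))), lwd = 2)
  invisible(x)
}
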