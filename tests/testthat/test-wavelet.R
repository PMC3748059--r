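sinusoid <- function(period, n = 128, shift = 0) {
  preprocess(sin(2 * pi * ((1:n) + shift) / period), log = FALSE)
}

test_that("preprocessing standardizes, logs and guards non-positive input", {
  set.seed(1)
  x <- exp(rnorm(64))
  z <- preprocess(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  # precipitation-style zeros need the offset
  r <- c(0, 0, rexp(30))
  expect_error(preprocess(r), "index 1")
  expect_silent(preprocess(r, zero_offset = 1))
  # scale changes of the input leave the standardized series unchanged
  expect_equal(preprocess(10 * x), preprocess(x))
  expect_error(preprocess(rep(2, 32)), "constant")
  expect_error(preprocess(x[1:10]), "length")
})

test_that("Morlet scales, periods and COI follow the stated conventions", {
  x <- sinusoid(8)
  cw <- cwt_morlet(x)
  # lambda for s = 1, omega0 = 6: 4*pi/(6 + sqrt(38)) = 1.0330
  expect_equal(cw$period[1] / cw$scale[1], 1.033044, tolerance = 1e-6)
  expect_equal(cw$scale, 2 * 2^((0:(length(cw$scale) - 1)) / 12))
  expect_true(all(diff(cw$scale) > 0))
  # COI: zero at both edges, maximal mid-series
  expect_equal(cw$coi[1], 0)
  expect_equal(cw$coi[128], 0)
  expect_equal(which.max(cw$coi), 64)
  expect_true(all(cw$power >= 0))
  expect_error(cwt_morlet(x[1:3]), "shorter")
})

test_that("the transform is linear to machine precision", {
  set.seed(2)
  x <- rnorm(100)
  a <- 3.7
  W1 <- cwt_morlet(a * x)$W
  W2 <- cwt_morlet(x)$W
  expect_equal(W1, a * W2, tolerance = 1e-13)
})

test_that("FFT implementation matches direct time-domain convolution", {
  set.seed(5)
  x <- preprocess(rnorm(64) + sin(2 * pi * (1:64) / 8), log = FALSE)
  cw <- cwt_morlet(x)
  # scales well inside the resolved band: spectral truncation and Gaussian
  # tail effects are below 1e-8 there
  for (starget in c(4, 5.66, 8)) {
    j <- which.min(abs(cw$scale - starget))
    Wd <- direct_cwt_scale(x, cw$scale[j])
    expect_lt(max(Mod(cw$W[j, ] - Wd)) / max(Mod(Wd)), 1e-8)
  }
})

test_that("sinusoid periods are recovered within one scale step", {
  for (P in c(4, 8, 16, 32)) {
    cw <- cwt_morlet(sinusoid(P))
    Pm <- cw$period[which.max(rowMeans(cw$power))]
    expect_lt(abs(Pm - P) / P, 0.06)  # dj = 1/12 => <= 6% grid error
  }
})

test_that("red-noise background is flat for white noise, peaked power found", {
  set.seed(6)
  w <- preprocess(rnorm(256), log = FALSE)
  cw <- cwt_morlet(w)
  m <- red_noise_significance(cw)
  expect_lt(abs(m$r1), 0.15)
  # near-zero r1: background ~1 at every scale
  expect_lt(max(abs(m$background - 1)), 0.3)
  # a strong 8-week oscillation is flagged at the 8-week period
  set.seed(7)
  x <- preprocess(sin(2 * pi * (1:128) / 8) + 0.2 * rnorm(128), log = FALSE)
  cs <- cwt_morlet(x)
  ms <- red_noise_significance(cs)
  j8 <- which.min(abs(cs$period - 8))
  expect_gt(mean(ms$mask[j8, cs$in_coi[j8, ]]), 0.9)
  # and mask is exactly the power/threshold comparison
  expect_identical(ms$mask, sweep(cs$power, 1, ms$threshold, `>`))
  expect_error(red_noise_significance(cs, x = rep(1, 128)), "degenerate")
})

test_that("cross-wavelet phase follows the arrow convention", {
  x <- sinusoid(16)
  cx <- cwt_morlet(x)
  # self-cross: zero phase, cross-power equals power
  self <- cross_wavelet(cx, cx)
  expect_equal(max(abs(self$phase_deg)), 0)
  expect_equal(self$power, cx$power)
  j <- which.min(abs(cx$period - 16))
  inc <- cx$in_coi[j, ]
  # quarter-period lead of the second series: +90 degrees
  lead4 <- cross_wavelet(cx, cwt_morlet(sinusoid(16, shift = 4)))
  expect_lt(max(abs(lead4$phase_deg[j, inc] - 90)), 5)
  # eighth-period lead: +45 degrees
  lead2 <- cross_wavelet(cx, cwt_morlet(sinusoid(16, shift = 2)))
  expect_lt(max(abs(lead2$phase_deg[j, inc] - 45)), 5)
  # quarter-period behind: -90 degrees
  lag4 <- cross_wavelet(cx, cwt_morlet(sinusoid(16, shift = -4)))
  expect_lt(max(abs(lag4$phase_deg[j, inc] + 90)), 5)
  # anti-phase: 180 degrees (up to wrap)
  anti <- cross_wavelet(cx, cwt_morlet(-x))
  expect_lt(max(abs(abs(anti$phase_deg[j, inc]) - 180)), 5)
  expect_true(all(lead4$phase_deg > -180 & lead4$phase_deg <= 180))
  # pointwise |Wxy| = |Wx||Wy|
  cy <- cwt_morlet(sinusoid(16, shift = 4))
  expect_equal(lead4$power, Mod(cx$W) * Mod(cy$W), tolerance = 1e-12)
  expect_error(cross_wavelet(cx, cwt_morlet(sinusoid(16, n = 64))),
               "mismatched")
})

test_that("interaction series is the preprocessed elementwise product", {
  set.seed(8)
  a <- exp(rnorm(64)); b <- exp(rnorm(64))
  expect_equal(interaction_series(a, rep(1, 64)), preprocess(a))
  expect_equal(interaction_series(a, b), interaction_series(b, a))
  expect_true(all(is.finite(interaction_series(a, b))))
  # synthetic defaults: tmin * hmin is positive so the log is defined
  m <- generate_climate(climate_params(seed = 9), 90)
  expect_silent(interaction_series(m$tmin_c, m$hmin_pct))
})

test_that("spectra serialize to long-format CSV", {
  x <- sinusoid(8, n = 64)
  cw <- cwt_morlet(x)
  m <- red_noise_significance(cw)
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(cw, p, mask = m, weeks = week_seq("2010-W01", 64))
  back <- utils::read.csv(p)
  expect_equal(nrow(back), length(cw$scale) * 64)
  expect_named(back, c("time", "scale", "period", "value", "week",
                       "significant", "in_coi"))
  expect_equal(back$value[1], cw$power[1, 1])
})
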