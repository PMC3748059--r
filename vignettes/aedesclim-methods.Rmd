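---
title: "Modeling climate-driven Aedes aegypti trap counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling climate-driven Aedes aegypti trap counts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aedesclim` analyzes weekly sticky-trap surveillance of adult female
*Aedes aegypti* against meteorological covariates. It combines a global view
— a negative-binomial regression estimating *average* lagged climate effects
— with a local view — a Morlet wavelet suite locating *transient*,
non-stationary associations in time and scale. This vignette explains the
models, the tunable parameters, the synthetic-data generator, and the design
choices that were genuinely open.

## The count model

The weekly number of captured females $y_t$ is modeled as negative binomial
with mean $\mu_t$ and overdispersion $\theta$ (variance
$\mu_t + \mu_t^2/\theta$), with log link

$$\log \mu_t = \log N_t + \beta_{ar}\, a_{t-1}
  + \beta_T\, T_{t-\ell_T} + \beta_H\, H_{t-\ell_H}
  + \beta_{int}\, T_{t-\ell_T} H_{t-\ell_H},$$

where $N_t$ is the number of traps inspected in week $t$ (an offset with
coefficient one, correcting for inhomogeneous sampling effort), $a_t =
y_t/\text{positive traps}_t$ is the per-trap abundance, $T$ is minimum
temperature (°C), $H$ minimum relative humidity (%), and $\ell_T, \ell_H \in
\{0,\dots,4\}$ weeks. **There is no intercept**, and lags beyond 4 weeks are
not considered because the adult lifespan is roughly 2–4 weeks. Two trap
denominators coexist deliberately: positive traps for the abundance index
and AR term, observed traps for the effort offset.

Two negative-binomial conventions circulate; this package fixes
**mean/size**: `dnbinom(size = theta, mu = mu)`, variance
$\mu + \mu^2/\theta$, so a single $\theta$ near 19 yields the
variance-to-mean ratio around 30 seen in such surveillance counts.

Fitting maximizes the joint likelihood in $(\beta, \theta)$ by alternating
IRLS with $\theta$ profiling (`MASS::glm.nb`); the reported AIC counts
$\theta$ as a parameter, $AIC = -2\ell + 2(p+1)$, so fixed-$\theta$ and
estimated-$\theta$ comparisons are internally consistent. Standard errors
come from the observed information; p-values are two-sided Wald tests.

### Modeling strategy

1. **Univariate screening** (`univariate_screen`): each of the eight
   meteorological variables, at each lag 0–4, is fitted as the sole
   covariate (offset, no intercept) and kept if $p < 0.05$, ranked by
   increasing p. Ties are broken by smaller lag, then variable name, so the
   ranking is deterministic. Per variable only the best lag is carried
   forward. Note a structural feature of intercept-free screening: any
   covariate whose scaled mean can absorb the baseline log-rate will appear
   "significant" whenever the per-trap rate differs from one. That is
   faithful to the screening design; the lag-discrimination power of the
   screen is therefore tested with centered anomalies.
2. **Selection** (`select_model`): every screened temperature variable is
   paired with every screened humidity variable (up to $3\times3 = 9$
   candidates), each with the AR(1) term and the pairwise interaction, and
   the minimum-AIC fit wins. At most one temperature and one humidity main
   effect per model limits collinearity. All candidates are refitted on an
   identical sample — the leading rows up to the *largest* lag among
   candidates are dropped for all of them — because AICs are only
   comparable on a common dataset.
3. **Diagnostics**: `acf_pacf` (Durbin–Levinson PACF, white-noise bands
   $\pm 1.96/\sqrt n$) applied to residuals.
4. **Forecasting** (`forecast_nb`): the fitted model is projected over a
   19-week (configurable) hold-out and scored by Spearman rank correlation.
   Two modes are provided because the choice is substantive: `one_step`
   (default) uses the observed per-trap abundance of the previous week —
   appropriate when the forecast is evaluated against the realized series
   weekly — while `iterated` propagates the model's own predicted
   abundance. Intervals combine coefficient uncertainty (delta method on
   the linear predictor; $\theta$ uncertainty is ignored, a second-order
   effect here) with negative-binomial quantiles.

### Interaction thresholds and growth regions

With an interaction, the partial effect of temperature,
$\beta_T + \beta_{int} H$, flips sign at $H^\* = -\beta_T/\beta_{int}$, and
the humidity effect flips at $T^\* = -\beta_H/\beta_{int}$
(`sign_change_thresholds`; undefined when $\beta_{int} = 0$). Outputs print
these at one decimal place, the meaningful precision.

`growth_condition` asks whether the model predicts *positive population
growth*: expected per-trap abundance above the previous week's value,
$\exp(\beta_{ar} y_{prev} + \beta_T T + \beta_H H + \beta_{int} T H) >
y_{prev}$. The effort offset cancels in this per-trap comparison, and the
same per-trap quantity is used on both sides, which resolves the
positive-vs-observed denominator mismatch. `growth_map` evaluates this on a
grid (default $T \in [10, 32]$ °C by 0.1, $H \in [30, 100]$ % by 0.5,
covering the observed ranges) and extracts the frontier — the least
humidity allowing growth at each temperature. Growth regions are nested
decreasing in $y_{prev}$ for $y_{prev} < 1/\beta_{ar}$, since the growth
condition rearranges to $\exp(g(T,H)) > y\,e^{-\beta_{ar} y}$ with the
right side increasing on that range; the scenario abundances used
(0.111, 0.56, 0.99 per trap) all sit below it.

## The wavelet suite

All series are log-transformed (a `zero_offset` handles exact zeros, e.g.
precipitation) and standardized before analysis (`preprocess`); scale
changes of the raw series therefore do not change the spectra. A `log =
FALSE` escape hatch exists for test signals with non-positive values, where
only the standardization is meaningful.

`cwt_morlet` implements the Morlet CWT ($\omega_0 = 6$) by FFT convolution
on the zero-padded series, with the energy normalization that makes
expected white-noise power flat across scales. Defaults follow the
long-established conventions for this transform: $\delta j = 1/12$, $s_0 =
2\delta t$, $J = \lfloor \log_2(n \delta t/s_0)/\delta j\rfloor$ — chosen
here because the analysis this package implements specifies none of its
own. The Fourier period is $\lambda = 4\pi s/(\omega_0 +
\sqrt{2+\omega_0^2}) \approx 1.033\,s$. The cone of influence uses the
$\sqrt 2 s$ e-folding distance of the wavelet envelope: a cell is
edge-unaffected when its period is below
$\lambda_{coi}(t) = 1.033\,d(t)/\sqrt 2$ with $d(t)$ the distance to the
nearer edge, so the COI is zero at both edges and maximal mid-series.
Padding is always non-empty (the length doubles when $n$ is already a power
of two) and is removed before returning.

**Red-noise significance** (`red_noise_significance`): the null is an AR(1)
process with lag-1 autocorrelation $r_1$ estimated from the series — the
ordinary sample autocorrelation, not smoothed variants; simpler, and the
calibration is verified by simulation in the test suite. The null spectrum
$P(\lambda) = (1-r_1^2)/(1+r_1^2-2 r_1\cos(2\pi \delta t/\lambda))$ scaled
by the series variance gives the pointwise threshold $P \cdot
\chi^2_2(0.95)/2$ for the complex transform. Under a simulated AR(1) null
about 95% of in-COI cells fall below the threshold (checked at
$\phi = 0.7$, $n = 128$, 200 replicates).

**Cross-wavelet** (`cross_wavelet`): $W_{xy} = W_x \overline{W_y}$. Phase is
reported so that **positive angles mean the second series leads**: 0° in
phase, +90° a quarter period ahead, ±180° anti-phase, −90° a quarter period
behind. The sign convention is pinned by constructed sinusoids in the
tests. The joint forcing of two covariates is analyzed via
`interaction_series`, the preprocessed elementwise product of the raw
series.

**Coherence** (`coherence`): $R^2 = |S(W_{xy}/s)|^2 / (S(|W_x|^2/s)\,
S(|W_y|^2/s))$ with smoothing $S$ Gaussian in time (sd $= s/\delta t$
samples per scale, applied in the frequency domain) and boxcar in scale
(width $0.6/\delta j$ scales). Because one positive-kernel operator smooths
numerator and denominator, Cauchy–Schwarz bounds $R^2$ in $[0,1]$ and
self-coherence is exactly one everywhere — both are tested. Significance
is Monte-Carlo: pairs of AR(1) surrogates matched to each input's $r_1$
are pushed through the identical computation; their in-COI values are
pooled per scale and the observed coherence is compared with the 95th
percentile (300 surrogates by default, configuration-exposed; scales with
no in-COI cells get an infinite threshold, i.e. are never flagged). The
smoothing windows and surrogate count are not dictated by the analysis
being reproduced, so they follow the defaults of the widely used coherence
toolboxes and remain arguments.

## The synthetic-data generator

No surveillance dataset ships with the package, so `generate_climate` and
`generate_counts` provide series with the statistical structure the
analysis assumes. The climate model is, per variable, a seasonal mean plus
a cosine annual cycle (period 52 weeks, warm peak in mid-January) plus
stationary AR(1) noise; the average and maximum temperature/humidity
summaries are positive offsets above the directly generated minima, which
enforces the within-week orderings by construction. Precipitation is a
winter-peaking dry-week Bernoulli with Gamma rain in wet weeks; humidity is
clipped to $[0,100]$ from the top down to preserve ordering.

Defaults emulate a sub-humid tropical surveillance setting: minimum
temperature averaging 19.36 °C, minimum humidity 55.93% (the most variable
humidity summary, total sd ≈ 7%), about 39% rain-free weeks, wind 2.9 m/s,
425 installed traps inspected with probability 0.97, ~90-week series. The
dry-week intercept (−0.9 on the logit scale) was calibrated so the
replicate-mean dry fraction matches 35 dry weeks per 90. The count
recursion uses the headline coefficients ($\beta_{ar} = 0.8344$, $\beta_T =
-0.0714$, $\beta_H = -0.0257$, $\beta_{int} = 0.0016$, $\theta = 19.11$,
$\ell_T = 4$, $\ell_H = 2$) and a 12-week burn-in so the recursion forgets
the initial abundance $a_0 = 0.58$.

Positive traps are simulated as $1 + \mathrm{Binomial}(N_t - 1,\,
1 - e^{-c\,\mu_t/N_t})$ with $c = 5.1$, a clustered-occupancy
approximation calibrated so the stationary per-trap abundance sits near
0.58 with an interior positive-trap fraction — the generator reproduces
the published summary level of the abundance index rather than strict
per-trap bookkeeping (with ~210 captures in 425 traps, a mean abundance of
0.58 per *positive* trap cannot arise from integer per-trap counts; the
index behaves as a per-inspected-trap rate and is emulated as such).

Two properties of the generator deserve emphasis:

* **Metastability.** An exponential AR feedback with $\beta_{ar} \approx
  0.83$ has a stable equilibrium near 0.7 per trap and an unstable one
  near 1.5–1.9 depending on season; sustained warm-humid spells can push
  the recursion past it, after which it diverges (the implementation
  raises an error when $|\log \mu_t/N_t| > 30$). The default seasonal
  amplitudes (temperature ±2 °C — the emulated setting showed little
  temperature variability — and minimum humidity ±8%) keep the escape
  probability below ~0.5% per 90-week replicate; larger amplitudes make
  escapes noticeably more frequent. Simulation studies in the package
  simply skip an escaped replicate.
* **Causal sparsity.** Only minimum temperature and minimum humidity enter
  the count mean. The other six covariates are generated with realistic
  marginal structure but are causally inert, which is what makes the
  screening step's type-I behavior testable (an inert covariate should be
  flagged in ~5% of null replicates, and is).

What the generator does **not** emulate: spatial trap structure,
observation gaps, vector-control interventions, the reported single-week
rainfall extreme (treated as a transcription artifact), or any
non-climatic driver. Passing tests on synthetic data therefore demonstrate
the *internal* consistency and calibration of the machinery, not the
field validity of any particular coefficient estimate.

## Numerical choices and degenerate inputs

* Lagged values are carried as explicit `NA` and dropped only at
  design-matrix construction, so every module sees full-length series.
* Screening cells that fail to fit are recorded, not fatal; selection
  errors only if all nine candidates fail.
* `fit_nb` errors on non-convergence (carrying the $\theta$ trace) and on
  non-finite estimates (separation/overflow).
* Constant series are rejected by `acf_pacf`, `preprocess` and the
  red-noise estimator (degenerate $r_1$).
* Coherence refuses sub-sample smallest scales (`s0 < dt`), where the time
  smoother would be degenerate.
* The week axis is strict: labels `YYYY-Www`, ISO 52/53-week years, gaps
  are an error rather than silently bridged.

## Problem sizes

The shipped test-suite and acceptance computations use the study-scale
sizes: 90-week series (plus a 19-week hold-out for forecasting), $n = 128$
for spectral checks, 100 refit replicates for coefficient recovery, 200
replicates for the two calibration rates, and reduced surrogate counts
(10–80) inside pipeline tests where only the plumbing is under test. A
full pipeline run at default surrogate count (300) takes on the order of
ten seconds.

## Known limitations

* Threshold estimates carry no uncertainty bands (a delta-method extension
  would be straightforward but is out of scope).
* Iterated forecasting propagates abundance through *observed* positive
  traps, so it still conditions on realized effort.
* The wavelet suite does not reconstruct or filter series, and
  cross-spectrum significance is surrogate-based rather than using the
  analytic cross-power distribution (uniformity across the suite was
  preferred).
* Quasi-likelihood, zero-inflated and Bayesian alternatives to the count
  model are out of scope.
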