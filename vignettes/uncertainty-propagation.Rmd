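---
title: "Propagating primary-model uncertainty into secondary thermal inactivation parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating primary-model uncertainty into secondary thermal inactivation parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoprop)
```

## The model and the problem

Thermal inactivation of a heat-labile substance at constant temperature is
described by the log-linear primary model
$$\log_{10} C = \log_{10} C_0 - t / D_T,$$
with $D_T$ the decimal reduction time (min). Its temperature dependence
follows the Bigelow secondary model
$$\log_{10} D_T = \log_{10} D_{T_{ref}} + (T_{ref} - T)/z,$$
with $z$ (°C) the temperature rise producing a tenfold drop in $D_T$.

Both stages are ordinary least-squares fits of a straight line. The package
regresses $y = \log_{10} D_T$ on $x = T_{ref} - T$, so the slope is $1/z$
and the intercept is $\log_{10} D_{T_{ref}}$: both parameters are direct
transforms of the coefficients. (The equivalent convention of regressing on
$T$ differs only in the slope's sign.) Interval half-widths of the
transformed parameters are mapped to the natural scale by the first-order
rule $\delta(f(x)) = |f'(x)|\,\delta(x)$:
$\delta(D_T) = D_T^2\,\delta(1/D_T)$, $\delta(z) = z^2\,\delta(1/z)$, and
$\delta(D_{T_{ref}}) = \ln(10)\,D_{T_{ref}}\,\delta(\log_{10} D_{T_{ref}})$,
where each $\delta(\cdot)$ on the right is the two-sided Student-t
coefficient interval ($t_{\alpha/2}$ on $n-2$ degrees of freedom,
$\alpha = 0.05$ by default). Mean-response and new-observation bands for
the secondary regression use the textbook forms
$t_{\alpha/2}\,\sigma_y\sqrt{1/N + (x_0-\bar x)^2/S_{xx}}$ and
$t_{\alpha/2}\,\sigma_y\sqrt{1 + 1/N + (x_0-\bar x)^2/S_{xx}}$ with
$S_{xx} = \sum_i (x_i - \bar x)^2$ the centred sum of squares — the only
reading under which the band formulas are dimensionally consistent.

The deterministic two-step fit uses only the mean $D_T$ per temperature.
Every $D_T$, however, carries its own regression CI, and ignoring it makes
the reported intervals of $D_{T_{ref}}$ and $z$ conditional on the means
being exact. `run_two_stage_mc()` quantifies what those intervals look like
when the $D_T$ uncertainty is taken seriously.

## The nested Monte Carlo scheme

Each tabulated $D_T$ is treated as normal with mean equal to the tabulated
value and $\sigma$ = (95% CI half-width) / `ci_to_sigma_factor`. The normal
is *discretized*: the central bin spans $[\mu - 0.25\sigma,
\mu + 0.25\sigma]$ and further $0.5\sigma$-wide bins extend symmetrically;
each bin is represented by its midpoint with the bin's normal mass. For
$\mu = 896.3$, $\sigma = 22.5$ (the 80 °C entry of the packaged table) the
central midpoint carries $\Phi(0.25)-\Phi(-0.25) \approx 20\%$, the
midpoint one $\sigma$ below about 12%, and the one at $2.5\sigma$ below
about 1%.

- **Stage 1.** Draw `n_outer` joint sets of one $D_T$ per temperature
  (independent across temperatures) and fit the secondary model to each,
  keeping every fit's $(D_{T_{ref}}, z)$ estimates *and* their delta-method
  CIs.
- **Stage 2.** Treat each outer estimate as the mean of its own normal
  ($\sigma$ = its CI / `ci_to_sigma_factor`), discretize the same way, and
  draw `n_inner` values. $D_{T_{ref}}$ and $z$ are sampled independently of
  each other.
- **Pooling.** The `n_outer × n_inner` values per parameter are summarized
  by their mean, SD and `ci95_half = summary_ci_factor × SD`.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `n_outer`, `n_inner` | 500, 500 | draws | stabilized well before this size (see the sensitivity analysis) |
| `t_ref` | 120 | °C | process-relevant reference; changing it moves $D_{T_{ref}}$, never $z$ |
| `ci_to_sigma_factor` | 2.0 | — | the packaged table's 80 °C CI (45.0 min) is exactly twice its stated σ (22.5 min); 1.96 or t-based values are alternatives |
| `summary_ci_factor` | 2.0 | — | mirror of the input convention; a percentile summary (2.5/97.5%) is available |
| `truncation_half_width_sigma` | 4.0 | σ | bins beyond ±4σ carry <0.01% each; residual tail mass is folded into the outermost bins |
| `alpha` | 0.05 | — | two-sided Student-t coefficient intervals, df = n − 2 |

The CI↔σ factor of 2 (rather than 1.96) is deliberately the convention the
packaged data were built with; both knobs are exposed because published
tables are inconsistent about whether "±95% CI" means $1.96\sigma$,
$2\sigma$ or a t-interval.

## Numerical choices

*Tail handling.* The discretization must truncate somewhere; folding the
residual tail mass into the outermost bins keeps the masses summing to 1
exactly and, by symmetry, keeps the mean of the discrete distribution at
$\mu$. The alternative (resampling out-of-range draws) renormalizes instead
of folding; at ±4σ the difference is below 10⁻⁴ in any bin mass.

*Stage-2 sampling.* The fitted parameters are resampled through the same
0.5σ discretization as stage 1, for internal consistency. Continuous
normal sampling (`stage2_sampling = "normal"`) is available; the two agree
on pooled CIs to within a few percent (the discretization adds
$h^2/12 \approx 2\%$ of $\sigma^2$ of grouping variance and removes a
little tail variance, nearly cancelling).

*Degenerate outer draws.* With very wide input CIs an outer D-value set can
lose its monotone temperature trend, making the secondary slope
non-positive and $z$ undefined. Such sets are rejected and redrawn from a
dedicated RNG substream, with the count reported in the result; the run
aborts if the rejection rate exceeds 20%, at which point the inputs are too
noisy for this scheme to mean anything. A strict `reject_policy = "error"`
is available.

*Reproducibility.* One root seed is hashed with named labels into
independent substreams — per temperature in stage 1, per parameter in
stage 2, per size in the sensitivity analysis — so identical (table,
config, seed) gives bit-identical results and components can be re-run in
isolation.

*Independence.* $D_{T_{ref}}$ and $z$ are deliberately sampled
independently in stage 2, ignoring their (typically negative) regression
correlation; this mirrors the procedure being modelled. Joint sampling
would narrow joint statements about both parameters but leaves the marginal
CIs reported here unchanged.

## The synthetic-data generator

`generate_isothermal()` draws
$\log_{10} C = \log_{10} C_0 - t/D + \varepsilon$,
$\varepsilon \sim N(0, \texttt{noise\_sd})$ i.i.d. per observation. Noise
lives on the log10 scale — the scale on which the model is linear and the
regression is performed; an option for noise on raw concentration is not
provided because the fitting pathway would then be misspecified by
construction, which is a separate study. The default design uses 7 time
points spanning two log reductions ($t$ from 0 to $2D$), a typical bench
layout; the raw designs behind the packaged D-value table were never
published, so this is a documented convention, not a recovered value.
`dt_sampling_distribution()` repeats generate-then-fit to expose the
sampling distribution of $\hat D_T$; at moderate noise (CV of
$\hat D_T \lesssim 10\%$) it is approximately normal (|skewness| < 0.5),
which is what justifies the normal input assumption of the Monte Carlo
scheme. The generator emulates homoscedastic, uncorrelated measurement
error only — no autocorrelation, heteroscedasticity, or detection limits —
so passing tests validate the machinery, not any claim about a particular
instrument.

## What the tests compute, and at what sizes

The test suite fits 8-point regressions, uses 500×500 (occasionally
100×100 and smaller) Monte Carlo runs, 500–50,000-draw sampler checks and
1000-replicate synthetic studies; the whole suite runs in seconds. The
sensitivity analysis compares 25×25 through 500×500 and checks that the
pooled CI half-widths change by less than 5% between 250×250 and 500×500.

## Known limitations

- The pooled stage-2 sample is a scale mixture across outer fits. With
  narrow input CIs it is indistinguishable from normal (|skewness| < 0.3,
  |excess kurtosis| < 0.5 at 250,000 draws). With strongly expanded input
  CIs it stays near-symmetric but develops visibly heavier tails (excess
  kurtosis up to ~0.9), so summarizing it by mean ± 2 SD is mildly
  conservative in the tails there.
- $z = 1/\text{slope}$ is a convex transform, so pooled $z$ means sit a few
  tenths of a °C above the deterministic estimate under wide input CIs
  (Jensen's inequality), well within one pooled SE.
- D-values entering from published tables are typically rounded; with
  1-decimal inputs the back-transformed $D_{T_{ref}}$ can differ from the
  value computed on unrounded data by ~0.1–0.2%.
- Only the log-linear primary and Bigelow secondary models are
  implemented. The fitting seam (`ols_fit` → transform) is the natural
  extension point for Weibull/Arrhenius variants, but they are out of
  scope here, as are weighted and errors-in-variables regression.
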