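# thermoprop

Thermal inactivation kinetics with realistic parameter uncertainty.

When a heat-labile substance (a nutrient, an enzyme, a microbial
population) is degraded isothermally, the standard two-step workflow fits a
log-linear **primary model** at each temperature,

    log10 C = log10 C0 − t / D_T

where `D_T` (the *decimal reduction time*, min) is the time needed for one
log10 reduction at temperature `T`, and then a Bigelow-type **secondary
model** across temperatures,

    log10 D_T = log10 D_Tref + (T_ref − T) / z

where `z` (°C) is the temperature rise that cuts `D_T` tenfold and `D_Tref`
is the D-value at a reference temperature. The catch: the second regression
uses only the *mean* `D_T` per temperature, so the reported confidence
intervals of `D_Tref` and `z` silently ignore the uncertainty of every
`D_T` estimate and can be far too narrow.

`thermoprop` implements both steps plus a **nested Monte Carlo procedure**
that propagates the per-temperature 95% CIs of `D_T` into the secondary
parameters: each `D_T` is replaced by a normal distribution discretized into
0.5 σ bins represented by their midpoints; `n_outer` joint D-value sets are
drawn and refitted, then `n_inner` values are drawn from each fitted
parameter's own interval, and the pooled `n_outer × n_inner` sample defines
the reported mean and 95% CI half-width (`2 × SD` by default). Confidence
and prediction bands for the secondary regression, delta-method interval
transforms, a synthetic survivor-curve generator and a Monte Carlo
sample-size sensitivity analysis round out the toolkit. It is aimed at food
scientists and predictive-microbiology modellers who report `z`/`D_Tref`
values with confidence intervals.

## Worked example

The package ships the l-carnitine thermal degradation D-value table
(8 temperatures, 80–130 °C) in two variants: the original narrow 95% CIs
and an intentionally expanded set.

```r
library(thermoprop)

tab <- carnitine_dt("original")
fit <- fit_secondary(tab, t_ref = 120)
fit
#> Bigelow secondary model (T_ref = 120 degC, 8 temperatures)
#>   D_Tref: 50.7 +/- 7.3 min
#>   z:      30.2 +/- 2.3 degC

mc <- run_two_stage_mc(tab, mc_config(n_outer = 500, n_inner = 500, seed = 1))
mc
#> Nested Monte Carlo propagation (500 x 500 draws, T_ref = 120 degC)
#>   D_Tref: 50.7 +/- 7.7 min   (deterministic 50.7 +/- 7.3)
#>   z:      30.2 +/- 2.4 degC  (deterministic 30.2 +/- 2.3)

run_two_stage_mc(carnitine_dt("expanded"), mc_config(seed = 1))
#> Nested Monte Carlo propagation (500 x 500 draws, T_ref = 120 degC)
#>   D_Tref: 50.5 +/- 13.8 min   (deterministic 50.7 +/- 7.3)
#>   z:      30.3 +/- 4.5 degC  (deterministic 30.2 +/- 2.3)
```

With narrow input CIs the propagated intervals barely move (±7.3 → ±7.7 min,
±2.3 → ±2.4 °C): the regression scatter dominates. With wide input CIs the
honest intervals are nearly twice the deterministic ones (±13.8 min,
±4.5 °C) — exactly the situation in which the traditional two-step recipe
understates the uncertainty. `sensitivity_analysis()` shows the pooled CIs
are stable from about 250 × 250 draws on, `validate_sampler()` checks the
discretized sampler recovers the input means and CIs, and
`predict(fit, temperature, interval = "prediction")` gives banded D-value
predictions at new temperatures.

A thin command-line wrapper is included:

```sh
exec/thermoprop mc --dt-table table.csv --tref 120 --n-outer 500 \
    --n-inner 500 --seed 1 --out results.json
```

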