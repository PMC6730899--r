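# egmr — fractional-order grey prediction for small samples

`egmr` fits and forecasts grey prediction models for short, nonnegative
time series — 10 to 30 annual observations, the regime where ARIMA or
learning-based forecasters cannot be estimated credibly. Its core is
EGM(1,1,r), the even grey model with a *fractional* accumulation order:
the raw series is accumulated with the r-order accumulation generation
operator (r-AGO),

    x^(r)(k) = sum_{i=1..k}  Gamma(r+k-i) / (Gamma(k-i+1) Gamma(r)) * x^(0)(i),

the grey difference equation `x^(r-1)(k) + a z^(r)(k) = b` is estimated
by least squares, the fitted recurrence
`x^(r)(k) = delta1 x^(r)(k-1) + delta2` (with
`delta1 = (1-0.5a)/(1+0.5a)`, `delta2 = b/(1+0.5a)`) is iterated, and the
inverse fractional difference maps the trajectory back to the original
scale. The order r is chosen by minimizing the mean relative simulation
error (MRSPE) with a seeded particle swarm or an exhaustive grid.
Classic GM(1,1) and discrete DGM(1,1) baselines, quasi-smoothness
modeling-condition diagnostics, a synthetic-series generator for
parameter-recovery testing, and a small CLI round out the package. It is
aimed at analysts forecasting short socio-economic or epidemiological
series and at anyone studying grey-systems methods.

## Worked example

The package ships its validation case study: China's total beef
consumption 1991–2015 (ten thousand tons), with the 2016–2018 actuals
withheld.

```r
library(egmr)
beef <- beef_fixture()

quasi_smooth_check(beef$train)
#> Quasi-smoothness check (epsilon = 0.8)
#>   rho(k), k = 3..25: max 0.718 <= 0.8
#>   lambda(k): max 0.989 < 1
#>   PASS: series is quasi-smooth

fit <- fit_egm11r(beef$train, r = 0.436213)
fit
#> EGM(1,1,r) fit on 25 points (1991..2015)
#>   order r: 0.436213
#>   coefficients: a =   0.01176737, b = 127.48141579
#>   recurrence: delta1 =   0.9883015, delta2 = 126.7357424
#>   MRSPE: 5.35 %

round(predict(fit, h = 3), 2)
#>   2016   2017   2018
#> 740.59 751.21 761.39
round(100 * holdout_mrpe(predict(fit, 3), beef$holdout), 2)
#> [1] 5.1

compare_models(beef$train, r = 0.436213)
#> Grey model comparison on 25 points
#>   EGM(1,1,r)  MRSPE   5.35%  (r = 0.436213 )
#>   GM(1,1)     MRSPE  12.26%
#>   DGM(1,1)    MRSPE  12.25%
```

Reading: the series passes the admissibility screen; at the fractional
order the in-sample mean relative error is 5.35%, less than half that of
either integer-order baseline; the three-year-ahead forecasts land
within ~5% of the withheld actuals. `grid_search_order()` or
`optimize_order_pso()` pick r automatically (on this series they find
r ≈ 0.514, slightly better in-sample than the order shown above — see
the methods vignette's replication notes). `write_report()` renders a
comparison table, forecasts, and an unrounded JSON summary;
`generate_synthetic()` manufactures exact-recurrence series for
parameter-recovery checks.

A command-line interface is installed at `exec/egmr`:

```sh
Rscript exec/egmr compare --fixture beef --order 0.436213 \
    --forecast 3 --outdir out/
```

Subcommands: `check`, `fit`, `compare`, `forecast`, `simulate`; flags
include `--input/--fixture`, `--order {auto-grid|auto-pso|FLOAT}`,
`--holdout N`, `--forecast N`, `--epsilon X`, `--strict-smoothness`,
`--seed N`, `--outdir DIR`.

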