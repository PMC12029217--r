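# clogfit

Modeling the clogging of constant-pressure membrane filtration from
cumulative volume–time curves: empirical fractional models with a
swarm + least-squares fitting engine, a full goodness-of-fit suite, and a
Hermia blocking-law diagnostic that identifies the fouling mechanism.

## Who this is for

Membrane and bioprocess engineers (protein or plasmid-DNA microfiltration,
water treatment, beverage clarification) who record cumulative permeate
volume `v` against time `t` during constant-pressure runs and want to

1. **predict** material accumulation and the asymptotic volume `v∞` at
   which filtration ceases, using flexible empirical models, and
2. **identify** the clogging mechanism from the unified blocking law

   d²t/dv² = k·(dt/dv)^N

   where the clogging index `N` marks the mechanism: `N = 0` cake
   filtration, `N = 1` intermediate blocking, `N = 1.5` standard blocking
   (in-pore constriction), `N = 2` complete blocking. Taking logarithms
   turns the law into a straight line, `ln(d²t/dv²) = N·ln(dt/dv) + C`,
   whose slope is `N` and whose intercept gives the clogging constant
   `k = e^C`.

The package ships eight empirical fractional volume–time models (rational
and exponential-saturation forms such as `v = a·tⁿ/(1 + b·tⁿ)`), fit by a
dragonfly-algorithm global search (10 restarts) with bounded
Levenberg–Marquardt refinement minimizing the relative root-mean-squared
error (nRMSE), and judged by SSR, R², VAF, RMSE/nRMSE, MAE/nMAE, Chi/nChi,
SEP and the calculated-vs-observed regression vector (α, β, R). See the
methods vignette (`vignettes/membrane-clogging.Rmd`) for the model
equations, algorithm details and design rationale.

## Worked example

Fit the workhorse rational model (model 6) to a bundled demonstration
series — a standard-blocking run emulating BSA microfiltration at 5 psi —
then identify the mechanism from the fitted curve:

```r
library(clogfit)

s <- make_demo_series()$db01_5psi   # 50 points over 85 min, 1% noise
fit <- fit_model(s, model = 6, fit_config(seed = 1))
fit
#> <clog_fit> model 6 (rational)
#>   parameters: a = 2.27963e-05, b = 0.103674, n = 1.008
#>   nRMSE = 0.870755 | R2 = 0.998563 (excellent; nRMSE excellent)

glance(fit)[, c("model_id", "nRMSE", "R2", "VAF", "SEP", "alpha", "beta", "R")]
#> # A tibble: 1 × 8
#>   model_id nRMSE    R2   VAF   SEP alpha        beta     R
#>   <chr>    <dbl> <dbl> <dbl> <dbl> <dbl>       <dbl> <dbl>
#> 1 6        0.871 0.999  99.9 0.871 0.999 0.000000182 0.999

estimate_clogging_index(fit)
#> <hermia_fit> N = 1.50715 (standard) | k = 39.8942 | R2 = 0.999994 | 200 points (analytic)
```

Reading the output: the model fits with nRMSE below 1% ("excellent" band)
and a calculated-vs-observed regression vector at its ideal (1, 0, 1); the
fitted exponent `n ≈ 1` makes the curve the integrated standard-blocking
law, and the analytic derivative route recovers a clogging index of ~1.5 —
standard blocking, which is indeed the mechanism this fixture was
generated from. `a/b ≈ 2.2e-4` estimates the asymptotic volume.

Other entry points: `fit_models()` fits and ranks several models;
`compare_models()` adds the standard-blocking and combined
intermediate→standard reference laws; `simulate_hermia()` and
`generate_series()` produce synthetic curves; `estimate_clogging_index()`
also accepts a raw series (central-difference route);
`autoplot()`/`tidy()`/`glance()`/`augment()` work on every result. A
command-line interface with `fit` / `simulate` / `identify` / `compare`
subcommands is installed at `inst/cli/clogfit`.

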