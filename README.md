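# tvvardyn

Time-varying vector autoregression for couples' daily-diary affect dynamics.

## What problem this solves

Dyadic diary studies record four affect series per couple — the female
partner's positive and negative relationship affect and the male partner's —
daily for 50–90 days.  The couple's *emotion dynamics* are the lag-1
dependencies among those series: a lag-1 VAR

> y_t = c + Φ y_{t−1} + ε_t

holds the autoregressive effects (inertia) on the diagonal of Φ and the
cross-lagged effects (one partner's affect driving the other's, or one
valence driving the other) off the diagonal.  Treating Φ as constant over
months of diary keeping is a strong assumption; `tvvardyn` estimates the
**time-varying** model

> y_t = c_t + Φ_t y_{t−1} + ε_t

with every intercept and every one of the 16 dynamic parameters a penalized
B-spline function of calendar day (varying-coefficient P-splines; smoothing
parameters chosen by generalized cross-validation).  Each dyad's fit is then
reduced to 16 means and 16 standard deviations of the parameter trajectories
over time, a parameter is flagged *time-varying* when its smooth is
significant **and** its effective degrees of freedom exceed 2, and the 32
summaries are related to later relationship quality (stepwise linear
regression) and relationship dissolution (stepwise logistic regression, with
odds ratios, classification accuracy, Cox & Snell and Nagelkerke R²), plus
covariate-adjusted refits.

The package is aimed at researchers analyzing intensive longitudinal dyadic
data and at methodologists studying the operating characteristics of
TV-VAR detection rules; a synthetic-data generator with known ground truth
(`simulation_spec()`, `simulate_cohort()`, scenario presets) makes every
pipeline stage testable without access to any particular study's raw data.

## Worked example

One couple simulated for 300 days whose Male PA → Female NA cross-lagged
effect swings sinusoidally (amplitude 0.4, one cycle per 150 days) while all
other dynamics are constant:

```r
library(tvvardyn)

spec <- scenario_sine(T = 300, amplitude = 0.4, period = 150, seed = 7)
s    <- simulate_dyad(spec, "couple01")
fit  <- fit_tvvar(s)            # k = 10 cubic P-splines, GCV-selected penalties
su   <- summarize_dynamics(fit)
su
#> <dynamics_summary couple01: 1 of 16 parameters time-varying>
names(which(su$timevarying_flags))
#> [1] "mpa_fna"
round(su$sds[c("mpa_fna", "fpa_fpa")], 3)
#> mpa_fna fpa_fpa
#>   0.300   0.000
fit$equation_fits$f_na$smooth_pvalues[["phi_m_pa"]]
#> [1] 2.1e-06
```

The oscillating parameter is the only one flagged; its estimated SD over
time (0.300) matches the generating trajectory's true SD (0.283), and the
constant Female PA autoregression is correctly reported with zero
variability.  Downstream, `outcome_dataset()` + `stepwise_select()` relate
such summaries to outcomes, and `run_pipeline()` executes the whole cohort
analysis (inclusion filter → per-dyad fits → summaries → outcome models)
from two CSV files or in-memory objects.

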