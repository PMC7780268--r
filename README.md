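# rmstsim

Monte-Carlo assessment of parametric survival extrapolation for health
technology assessment.

Economic models of new cancer therapies need mean survival over a horizon
of decades, but pivotal trials observe only a few years of heavily censored
follow-up. The standard workflow fits a set of parametric survival models
to the censored data, selects one by goodness of fit (AIC/BIC), and
integrates its curve to the model horizon — the restricted mean survival
time, RMST(h) = ∫₀ʰ S(t) dt. `rmstsim` turns the obvious validation
question into a reusable, tested pipeline: *when the true distribution is
known, how accurate are the extrapolated RMSTs, and do information criteria
pick good models?*

The package is aimed at biostatisticians and HTA analysts. It provides:

* **Eight candidate families** — exponential, Weibull, log-normal,
  log-logistic, gamma, generalized gamma (Prentice μ, σ, Q), Gompertz,
  generalized F — with survival, density, hazard, quantile, sampling and
  RMST under the `stats`/`flexsurv` parameterizations, including stable
  routing at the nesting boundaries (Q → 0, P → 0).
* **A trial simulator**: event times from a known source distribution;
  staggered accrual with exponentially increasing recruitment density over
  the recruitment period; administrative censoring at a fixed trial end;
  independent exponential loss to follow-up. Each replicate yields matched
  complete and trial-censored datasets.
* **A censored-ML fitting engine**: BFGS on log-transformed parameters,
  warm starts along the nesting hierarchy, deterministic jittered restarts,
  and explicit convergence vetting; AIC = −2logL + 2K and Schwarz
  BIC = −2logL + K·log(n) (a doubled-penalty variant is available).
* **Selection and ADEMP performance measures**: per-replicate best model
  under AIC/BIC/log-likelihood; bias, empirical SE, MSE, Monte-Carlo SE,
  percentiles and share of estimates within ±10% of the true RMST, per
  model and per criterion; criterion-agreement analysis.
* **Orchestration**: YAML study configurations, per-replicate seed
  substreams (bitwise reproducible, order-independent), CSV result tables
  plus a run manifest, and a thin CLI (`inst/scripts/rmstsim`) with
  `simulate`, `fit`, `run` and `summarize` subcommands.

## Worked example

A low-event adjuvant-trial setting: 2400 patients, 23-month accrual
(rate 0.1/month), loss to follow-up 0.002/month, trial end at 46 months,
RMST horizon 624 months, exponential source calibrated so the true RMST is
376.8 months:

```r
library(rmstsim)

rate <- calibrate_exponential_rate(376.8, 624)   # 0.00177985
cfg <- scenario_config(
  "pertuzumab_exponential", surv_dist("exponential", rate = rate),
  n_patients = 2400, recruit_period = 23, recruit_rate = 0.1,
  ltf_rate = 0.002, max_followup = 46, horizon = 624,
  n_sim = 150, seed = 7)

res <- run_scenario(cfg, mode = "trial")
res$performance_models[res$performance_models$family %in%
                         c("exponential", "lognormal"),
                       c("family", "mean", "emp_se", "pct_within_band")]
#>        family     mean   emp_se pct_within_band
#>   exponential 377.1445 15.56836      98.6666667
#>     lognormal 476.7046 19.25014       0.6666667

fr <- selection_frequencies(res$selections)
fr[fr$family == "exponential" & fr$criterion %in% c("aic", "bic"), ]
#>   criterion      family   n     share
#> 1       aic exponential  96 0.6400000
#> 8       bic exponential 146 0.9733333
```

Reading: the correctly specified exponential recovers the 376.8-month truth
essentially unbiasedly (mean 377.1, ~99% of estimates within ±10%), while
the misspecified log-normal overestimates by ~26% with almost no estimates
in the band — on data it fits almost as well in-sample. BIC prefers the
exponential in ~97% of replicates versus ~64% for AIC: with only ~5% of
patients having events, the heavier penalty protects against overfitting
the censored stretch.

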