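## Shared fixtures: scenario constructors mirroring the two trial settings
## whose parameters are fully determined by published values, plus a
## fabricated fit-result builder for selection-logic tests.

pertuzumab_scenario <- function(n_sim = 10L, seed = 42L, n_patients = 2400L) {
  rate <- calibrate_exponential_rate(376.8, 624)
  scenario_config("pertuzumab_exponential",
                  surv_dist("exponential", rate = rate),
                  n_patients = n_patients, recruit_period = 23,
                  recruit_rate = 0.1, ltf_rate = 0.002, max_followup = 46,
                  horizon = 624, n_sim = n_sim, seed = seed)
}

## Accrual/censoring chosen to reproduce the trial's observed follow-up
## maturity (18-month trial end, ~79% of patients with events).
pembrolizumab_scenario <- function(n_sim = 10L, seed = 42L, n_patients = 542L) {
  scenario_config("pembrolizumab_exponential",
                  surv_dist("exponential", rate = 1 / 5.6),
                  n_patients = n_patients, recruit_period = 12,
                  recruit_rate = 0.2, ltf_rate = 0.002, max_followup = 18,
                  horizon = 420, n_sim = n_sim, seed = seed)
}

## A minimal fit_result stand-in for exercising selection logic without
## running the optimizer.
fake_fit <- function(family, loglik, k, n, converged = TRUE, rmst = 10,
                     bic_variant = "standard") {
  ic <- information_criteria(loglik, k, n, bic_variant)
  structure(list(family = family, pars = NULL, loglik = loglik, k = k,
                 n_obs = n, aic = ic$aic, bic = ic$bic,
                 converged = converged,
                 rmst_estimate = if (converged) rmst else NA_real_,
                 diagnostics = list()),
            class = "fit_result")
}

## Representative valid parameter sets for each family.
reference_dists <- function() {
  list(
    exponential = surv_dist("exponential", rate = 0.178571),
    weibull = surv_dist("weibull", shape = 1.3, scale = 20),
    lognormal = surv_dist("lognormal", meanlog = 2.5, sdlog = 0.9),
    loglogistic = surv_dist("loglogistic", shape = 1.8, scale = 15),
    gamma = surv_dist("gamma", shape = 2.2, rate = 0.15),
    gengamma = surv_dist("gengamma", mu = 2.8, sigma = 0.7, Q = 0.8),
    gompertz = surv_dist("gompertz", shape = 0.05, rate = 0.02),
    genf = surv_dist("genf", mu = 2.5, sigma = 0.8, Q = 0.5, P = 0.6))
}
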