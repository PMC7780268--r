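#' True RMST of a scenario
#'
#' The estimand: the RMST of the source distribution at the scenario's
#' economic-model horizon.
#'
#' @param cfg A [scenario_config()].
#' @return True RMST in months.
#' @export
true_rmst <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  rmst(cfg$source, cfg$horizon)
}

#' Share of estimates within a relative band of the truth
#'
#' `100 * #\{|est - theta| <= frac * theta\} / n`, boundary inclusive.
#'
#' @param estimates RMST estimates (months); `NA`s are dropped.
#' @param theta True RMST (> 0).
#' @param frac Relative half-width of the band (default 0.10).
#' @return Percentage in `[0, 100]`.
#' @export
pct_within_band <- function(estimates, theta, frac = 0.10) {
  stopifnot(theta > 0)
  est <- estimates[!is.na(estimates)]
  if (length(est) == 0) return(NA_real_)
  100 * mean(abs(est - theta) <= frac * theta)
}

#' ADEMP performance summary of RMST estimates
#'
#' Monte-Carlo performance measures of an estimator against the true RMST:
#' bias of the mean and median estimate (absolute and percentage), empirical
#' 5th/95th percentiles (linear interpolation), mean squared error,
#' empirical standard error (sample SD, denominator `n - 1`), Monte-Carlo
#' standard error of the mean estimate (`emp_se / sqrt(n)`), and the share
#' of estimates within a relative band of the truth.
#'
#' @param estimates RMST estimates across replicates (months); `NA`s (failed
#'   fits / excluded replicates) are dropped, and the number retained is
#'   reported as `n_included`.
#' @param theta True RMST (months, > 0).
#' @param band Relative half-width for [pct_within_band()] (default 0.10).
#' @return One-row `data.frame`: `n_included`, `mean`, `bias`, `pct_bias`,
#'   `p5`, `p95`, `median`, `median_bias`, `mse`, `mcse`, `emp_se`,
#'   `pct_within_band`.
#' @export
summarize_performance <- function(estimates, theta, band = 0.10) {
  stopifnot(theta > 0)
  est <- estimates[!is.na(estimates)]
  n <- length(est)
  if (n < 2)
    stop("need at least 2 estimates to summarize spread")
  m <- mean(est)
  md <- median(est)
  emp_se <- sd(est)
  qq <- quantile(est, c(0.05, 0.95), names = FALSE)
  data.frame(
    n_included = n,
    mean = m,
    bias = m - theta,
    pct_bias = 100 * (m - theta) / theta,
    p5 = qq[1], p95 = qq[2],
    median = md,
    median_bias = md - theta,
    mse = mean((est - theta)^2),
    mcse = emp_se / sqrt(n),
    emp_se = emp_se,
    pct_within_band = pct_within_band(est, theta, band))
}

#' @importFrom stats median var
NULL
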