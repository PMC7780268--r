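#' Define a simulated-trial scenario
#'
#' Bundles everything needed to simulate one arm of a trial and judge the
#' accuracy of extrapolated RMST estimates: the source event-time
#' distribution, cohort size, accrual pattern, censoring mechanisms, the
#' RMST horizon of the economic model, and the replicate count and seed.
#'
#' The follow-up model has three competing mechanisms per patient:
#' an event time drawn from `source`; loss to follow-up drawn from an
#' exponential with rate `ltf_rate`; and administrative censoring at
#' `max_followup - r`, where `r` is the patient's recruitment time on the
#' trial clock.  Recruitment times follow an exponentially increasing
#' density over `[0, recruit_period]` (multicenter ramp-up).
#'
#' @param label Unique scenario label (used to derive per-scenario seed
#'   streams).
#' @param source A [surv_dist()] describing the proper source distribution.
#' @param n_patients Cohort size (>= 2).
#' @param recruit_period Recruitment duration R in months (> 0).
#' @param recruit_rate Accrual growth rate per month (>= 0; 0 = uniform
#'   accrual).
#' @param ltf_rate Loss-to-follow-up exponential rate per month (>= 0; 0 =
#'   no loss to follow-up).
#' @param max_followup Trial end time measured from start of recruitment
#'   (months); must exceed `recruit_period`.
#' @param horizon RMST integration horizon (months); at least `max_followup`.
#' @param n_sim Number of Monte-Carlo replicates (>= 1).
#' @param seed Scenario master seed (integer).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(label, source, n_patients, recruit_period,
                            recruit_rate, ltf_rate, max_followup, horizon,
                            n_sim = 1000L, seed = 1L) {
  stopifnot(is.character(label), nzchar(label))
  if (!inherits(source, "surv_dist")) stop("source must be a 'surv_dist'")
  if (source$family == "gompertz" && source$pars[["shape"]] < 0)
    stop("source distribution must be proper")
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (recruit_period <= 0) stop("recruit_period must be > 0")
  if (recruit_rate < 0 || ltf_rate < 0) stop("rates must be >= 0")
  if (recruit_period >= max_followup)
    stop("recruit_period must be smaller than max_followup, otherwise some ",
         "patients would be enrolled after the trial ends")
  if (horizon < max_followup) stop("horizon must be >= max_followup")
  if (n_sim < 1) stop("n_sim must be >= 1")
  structure(list(label = label, source = source,
                 n_patients = as.integer(n_patients),
                 recruit_period = recruit_period, recruit_rate = recruit_rate,
                 ltf_rate = ltf_rate, max_followup = max_followup,
                 horizon = horizon, n_sim = as.integer(n_sim),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s\n", x$label))
  cat(sprintf("  source: %s(%s)\n", x$source$family,
              paste(sprintf("%s = %g", names(x$source$pars), x$source$pars),
                    collapse = ", ")))
  cat(sprintf("  n = %d, accrual %g mo (rate %g), ltf rate %g, trial end %g mo\n",
              x$n_patients, x$recruit_period, x$recruit_rate, x$ltf_rate,
              x$max_followup))
  cat(sprintf("  RMST horizon %g mo, %d replicates, seed %d\n",
              x$horizon, x$n_sim, x$seed))
  invisible(x)
}

#' Sample patient recruitment times
#'
#' Recruitment times on `[0, period]` follow the exponentially increasing
#' density `f(r) = rate * exp(rate * r) / (exp(rate * period) - 1)`,
#' mimicking accelerating multicenter accrual; sampling is by inverse CDF.
#' `rate = 0` degenerates to uniform accrual.
#'
#' @param n Number of patients.
#' @param period Recruitment duration (months, > 0).
#' @param rate Accrual growth rate (per month, >= 0).
#' @return `n` recruitment times in `[0, period]`.
#' @export
sample_recruitment_times <- function(n, period, rate) {
  if (period <= 0) stop("period must be > 0")
  if (rate < 0) stop("rate must be >= 0")
  u <- runif(n)
  if (rate == 0) return(u * period)
  log1p(u * expm1(rate * period)) / rate
}

#' Sample loss-to-follow-up times
#'
#' Exponential censoring times with a low hazard, independent of the event
#' process.  `rate = 0` returns `Inf` (no loss to follow-up).
#'
#' @param n Number of patients.
#' @param rate Exponential rate (per month, >= 0).
#' @return `n` positive times (possibly `Inf`).
#' @export
sample_ltf_times <- function(n, rate) {
  if (rate < 0) stop("rate must be >= 0")
  if (rate == 0) return(rep(Inf, n))
  rexp(n, rate)
}

#' Apply trial censoring to complete event times
#'
#' Each patient's follow-up ends at the earliest of the event, loss to
#' follow-up, and the administrative cut-off `max_followup - r` (the trial
#' ends at a fixed calendar time; the patient clock starts at recruitment).
#' Ties resolve to the event.
#'
#' @param event_times Positive event times (patient clock).
#' @param recruit_times Recruitment times, all `< max_followup`.
#' @param ltf_times Loss-to-follow-up times (may be `Inf`).
#' @param max_followup Trial end on the trial clock (months).
#' @return A `data.frame` with columns `time` (observed follow-up, months)
#'   and `status` (1 = event, 0 = censored).
#' @export
apply_trial_censoring <- function(event_times, recruit_times, ltf_times,
                                  max_followup) {
  n <- length(event_times)
  if (length(recruit_times) != n || length(ltf_times) != n)
    stop("event, recruitment and loss-to-follow-up vectors must have equal length")
  admin <- max_followup - recruit_times
  if (any(admin <= 0))
    stop("configuration error: some patients are recruited at or after the ",
         "trial end (recruit_period >= max_followup)")
  cens <- pmin(ltf_times, admin)
  status <- as.integer(event_times <= cens)
  data.frame(time = pmin(event_times, cens), status = status)
}

#' Generate one simulation replicate of a trial scenario
#'
#' Draws the complete cohort (event time, recruitment time, loss to
#' follow-up per patient) and returns both the complete dataset (every event
#' observed) and the trial-censored dataset.  Fully reproducible from
#' `(cfg$seed, cfg$label, index)`; replicates are independent substreams, so
#' they can be generated in any order.
#'
#' @param cfg A [scenario_config()].
#' @param index Replicate index (1-based).
#' @return A list with elements `complete` and `censored` (two-column
#'   survival `data.frame`s), `n_events` (events in the censored set) and
#'   `degenerate` (`TRUE` if the censored set has zero events and must be
#'   excluded from fitting).
#' @export
generate_replicate <- function(cfg, index) {
  stopifnot(inherits(cfg, "scenario_config"), index >= 1)
  set.seed(derive_seed(cfg$seed, cfg$label, index))
  n <- cfg$n_patients
  ev <- sample_event_times(cfg$source, n)
  rec <- sample_recruitment_times(n, cfg$recruit_period, cfg$recruit_rate)
  ltf <- sample_ltf_times(n, cfg$ltf_rate)
  censored <- apply_trial_censoring(ev, rec, ltf, cfg$max_followup)
  complete <- data.frame(time = ev, status = 1L)
  n_events <- sum(censored$status)
  list(complete = complete, censored = censored, n_events = n_events,
       degenerate = n_events == 0L)
}

## Deterministic 31-bit seed from (master seed, scenario label, replicate
## index).  All arithmetic stays below 2^53 so it is exact in doubles.
derive_seed <- function(master, label, index) {
  m <- 2147483629
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% m
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + h) %% m
  s <- (s * 69621 + as.numeric(index)) %% m
  as.integer(s)
}

#' Write / read a survival dataset as delimited text
#'
#' Two-column comma-separated table with header `time,status`, the de facto
#' exchange format for right-censored single-arm data.  The reader validates
#' that all times are positive and finite and all statuses are 0/1.
#'
#' @param d A `data.frame` with columns `time` and `status`.
#' @param path File path.
#' @return `write_survival_table` returns `path` invisibly;
#'   `read_survival_table` returns the validated `data.frame`.
#' @export
write_survival_table <- function(d, path) {
  stopifnot(all(c("time", "status") %in% names(d)))
  utils::write.csv(d[, c("time", "status")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_table
#' @export
read_survival_table <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "status") %in% names(d)))
    stop("survival table must have columns 'time' and 'status'")
  if (any(!is.finite(d$time)) || any(d$time <= 0))
    stop("all times must be positive and finite")
  if (!all(d$status %in% c(0L, 1L)))
    stop("status must be 0 (censored) or 1 (event)")
  d$status <- as.integer(d$status)
  d[, c("time", "status")]
}
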