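#' Calibrate an exponential rate from a target RMST
#'
#' Inverts the exponential closed form `RMST(h) = (1 - exp(-rate*h))/rate`
#' by root-finding, so a scenario can be specified by its published true
#' RMST and horizon alone.
#'
#' @param target_rmst Target RMST (months), `0 < target_rmst < horizon`.
#' @param horizon Integration horizon (months).
#' @return The exponential rate (per month).
#' @examples
#' calibrate_exponential_rate(376.8, 624)
#' @export
calibrate_exponential_rate <- function(target_rmst, horizon) {
  stopifnot(target_rmst > 0, target_rmst < horizon)
  uniroot(function(l) (1 - exp(-horizon * l)) / l - target_rmst,
          interval = c(1e-10, 10), tol = 1e-14)$root
}

#' Run one scenario of the simulation study
#'
#' The per-scenario ADEMP loop: for each replicate, generate the cohort,
#' take the complete or trial-censored view, fit the candidate families by
#' censored maximum likelihood, record per-fit RMST and information
#' criteria, and select the preferred model under AIC, BIC and
#' log-likelihood.  Afterwards, performance is summarized per model (over
#' that model's converged fits) and per criterion (over replicates where
#' selection succeeded).  Bitwise reproducible from the scenario seed;
#' replicates use independent derived substreams.
#'
#' @param cfg A [scenario_config()].
#' @param mode `"trial"` (censored follow-up) or `"complete"`.
#' @param families Candidate families to fit (default all 8).
#' @param bic_variant Passed to [information_criteria()].
#' @param reps Replicate-count override (default `cfg$n_sim`).
#' @param progress Print progress every 1000 replicates.
#' @return An object of class `scenario_result`: data frames `fits`,
#'   `selections`, `performance_models`, `performance_criteria`,
#'   `convergence` (per-family success rates), list `agreement` (AIC vs
#'   BIC), scalars `true_rmst`, `n_degenerate`, and `meta`.
#' @export
run_scenario <- function(cfg, mode = c("trial", "complete"),
                         families = family_names(),
                         bic_variant = c("standard", "printed"),
                         reps = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  mode <- match.arg(mode)
  bic_variant <- match.arg(bic_variant)
  reps <- as.integer(reps %||% cfg$n_sim)
  stopifnot(reps >= 1)
  theta <- true_rmst(cfg)
  t0 <- proc.time()[["elapsed"]]

  fit_rows <- vector("list", reps)
  sel_rows <- vector("list", reps)
  n_degenerate <- 0L
  for (r in seq_len(reps)) {
    gen <- generate_replicate(cfg, r)
    dat <- if (mode == "trial") gen$censored else gen$complete
    if (sum(dat$status) == 0L) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    fits <- fit_all(dat, horizon = cfg$horizon, families = families,
                    bic_variant = bic_variant,
                    jitter_seed = derive_seed(cfg$seed, paste0(cfg$label, "#fit"), r))
    fit_rows[[r]] <- fits_table(fits, replicate = r)
    sel_rows[[r]] <- do.call(rbind, lapply(c("aic", "bic", "loglik"),
      function(cr) select_model(fits, cr, replicate = r)))
    if (progress && r %% 1000 == 0)
      message(sprintf("[%s/%s] replicate %d/%d", cfg$label, mode, r, reps))
  }
  fits_df <- do.call(rbind, fit_rows)
  sel_df <- do.call(rbind, sel_rows)

  perf_models <- do.call(rbind, lapply(split(fits_df, fits_df$family), function(g) {
    est <- g$rmst[g$converged]
    if (sum(!is.na(est)) < 2) return(NULL)
    cbind(family = g$family[1], summarize_performance(est, theta))
  }))
  if (!is.null(perf_models)) {
    perf_models <- perf_models[order(match(perf_models$family, family_names())), ]
    rownames(perf_models) <- NULL
  }

  perf_criteria <- NULL
  if (!is.null(sel_df) && nrow(sel_df) > 0) {
    perf_criteria <- do.call(rbind, lapply(split(sel_df, sel_df$criterion), function(g) {
      est <- g$rmst
      if (sum(!is.na(est)) < 2) return(NULL)
      cbind(criterion = g$criterion[1], summarize_performance(est, theta))
    }))
    if (!is.null(perf_criteria)) rownames(perf_criteria) <- NULL
  }

  conv <- do.call(rbind, lapply(split(fits_df, fits_df$family), function(g) {
    data.frame(family = g$family[1], n_attempted = nrow(g),
               n_converged = sum(g$converged),
               success_rate = mean(g$converged))
  }))
  conv <- conv[order(match(conv$family, family_names())), ]
  rownames(conv) <- NULL

  agreement <- if (!is.null(sel_df) && nrow(sel_df) > 0)
    criteria_agreement(sel_df, theta) else NULL

  structure(list(
    label = cfg$label, mode = mode, true_rmst = theta,
    fits = fits_df, selections = sel_df,
    performance_models = perf_models, performance_criteria = perf_criteria,
    convergence = conv, agreement = agreement,
    n_replicates = reps, n_degenerate = n_degenerate,
    meta = list(seed = cfg$seed, bic_variant = bic_variant,
                families = families,
                elapsed_s = proc.time()[["elapsed"]] - t0)
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (%s follow-up), %d replicates, true RMST %.3f\n",
              x$label, x$mode, x$n_replicates, x$true_rmst))
  if (!is.null(x$performance_models)) {
    cat("Per-model performance:\n")
    print(x$performance_models, digits = 4)
  }
  invisible(x)
}

#' Define a full simulation study
#'
#' @param scenarios List of [scenario_config()] with unique labels.
#' @param mode `"trial"`, `"complete"`, or `"both"`.
#' @param bic_variant Passed to [information_criteria()].
#' @param reps Optional replicate-count override applied to every scenario.
#' @param seed Optional master seed; when given, each scenario's seed is
#'   derived from `(seed, label)` so scenario order is irrelevant.
#' @param families Candidate families to fit.
#' @return An object of class `study_config`.
#' @export
study_config <- function(scenarios, mode = c("trial", "complete", "both"),
                         bic_variant = c("standard", "printed"),
                         reps = NULL, seed = NULL,
                         families = family_names()) {
  mode <- match.arg(mode)
  bic_variant <- match.arg(bic_variant)
  stopifnot(is.list(scenarios),
            all(vapply(scenarios, inherits, logical(1), "scenario_config")))
  labels <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("scenario labels must be unique")
  if (!is.null(reps) && reps < 1) stop("replicate override must be >= 1")
  if (!is.null(seed)) {
    scenarios <- lapply(scenarios, function(cfg) {
      cfg$seed <- derive_seed(seed, cfg$label, 0L)
      cfg
    })
  }
  structure(list(scenarios = scenarios, mode = mode,
                 bic_variant = bic_variant, reps = reps, seed = seed,
                 families = families),
            class = "study_config")
}

#' Run a full study
#'
#' Executes every scenario in the requested follow-up mode(s).  Each
#' scenario uses its own derived seed stream, so results per scenario do not
#' depend on study composition or ordering.
#'
#' @param study A [study_config()].
#' @param progress Print scenario-level progress.
#' @return A list of class `results_bundle`: `results` (list of
#'   `scenario_result`, named `<label>.<mode>`) and `manifest` (seed,
#'   configuration echo, completion list).
#' @export
run_study <- function(study, progress = FALSE) {
  stopifnot(inherits(study, "study_config"))
  modes <- if (study$mode == "both") c("trial", "complete") else study$mode
  results <- list()
  for (cfg in study$scenarios) {
    for (m in modes) {
      if (progress) message(sprintf("running %s (%s follow-up)", cfg$label, m))
      results[[paste(cfg$label, m, sep = ".")]] <-
        run_scenario(cfg, mode = m, families = study$families,
                     bic_variant = study$bic_variant, reps = study$reps,
                     progress = progress)
    }
  }
  manifest <- list(
    master_seed = study$seed,
    mode = study$mode, bic_variant = study$bic_variant,
    reps_override = study$reps,
    scenarios = lapply(study$scenarios, scenario_to_list),
    completed = names(results),
    package_version = as.character(utils::packageVersion("rmstsim")))
  structure(list(results = results, manifest = manifest),
            class = "results_bundle")
}

#' Write study results to a directory
#'
#' One CSV per table per scenario-mode (`<label>_<mode>_{fits, selections,
#' performance_models, performance_criteria, convergence}.csv`) plus a YAML
#' `manifest.yaml` echoing the configuration and master seed.  Existing
#' files are overwritten (idempotent).
#'
#' @param bundle A `results_bundle` from [run_study()], or a single
#'   `scenario_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  if (inherits(bundle, "scenario_result"))
    bundle <- structure(list(results = setNames(list(bundle),
                                                paste(bundle$label, bundle$mode, sep = ".")),
                             manifest = list(scenarios = "single-scenario export")),
                        class = "results_bundle")
  stopifnot(inherits(bundle, "results_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (key in names(bundle$results)) {
    res <- bundle$results[[key]]
    stem <- file.path(dir, gsub("[^A-Za-z0-9_.-]", "_", key))
    tabs <- list(fits = res$fits, selections = res$selections,
                 performance_models = res$performance_models,
                 performance_criteria = res$performance_criteria,
                 convergence = res$convergence)
    for (nm in names(tabs)) {
      if (is.null(tabs[[nm]])) next
      ok <- tryCatch({
        utils::write.csv(tabs[[nm]], paste0(stem, "_", nm, ".csv"),
                         row.names = FALSE)
        TRUE
      }, error = function(e)
        stop(sprintf("failed writing %s_%s.csv: %s", stem, nm,
                     conditionMessage(e))))
    }
  }
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

scenario_to_list <- function(cfg) {
  list(label = cfg$label, family = cfg$source$family,
       params = as.list(cfg$source$pars),
       n_patients = cfg$n_patients, recruit_period = cfg$recruit_period,
       recruit_rate = cfg$recruit_rate, ltf_rate = cfg$ltf_rate,
       max_followup = cfg$max_followup, horizon = cfg$horizon,
       n_sim = cfg$n_sim, seed = cfg$seed)
}

scenario_from_list <- function(x) {
  src <- do.call(surv_dist, c(list(x$family), x$params))
  scenario_config(label = x$label, source = src, n_patients = x$n_patients,
                  recruit_period = x$recruit_period,
                  recruit_rate = x$recruit_rate, ltf_rate = x$ltf_rate,
                  max_followup = x$max_followup, horizon = x$horizon,
                  n_sim = x$n_sim %||% 1000L, seed = x$seed %||% 1L)
}

#' Read / write a study configuration file
#'
#' Plain-text YAML with a `study` block (mode, BIC variant, master seed,
#' optional replicate override) and a `scenarios` list.  Each scenario block
#' needs `label`, `family`, `params` (named source parameters), and the
#' cohort/censoring fields of [scenario_config()].  A bundled default
#' configuration with the censoring parameters of the four reference trials
#' ships at `system.file("extdata", "trial_scenarios.yaml", package =
#' "rmstsim")`; source-distribution parameters for non-exponential scenarios
#' are deliberately left to the user.
#'
#' @param path Configuration file path.
#' @param study A [study_config()] (for writing).
#' @return `read_study_config` returns a [study_config()].
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || length(cfg$scenarios) == 0)
    stop("configuration has no scenarios")
  scen <- lapply(cfg$scenarios, function(x) {
    if (is.null(x$params))
      stop(sprintf(
        "scenario '%s' has no source parameters; supply 'params' (they are a required user input)",
        x$label %||% "?"))
    scenario_from_list(x)
  })
  st <- cfg$study %||% list()
  study_config(scen,
               mode = st$mode %||% "trial",
               bic_variant = st$bic_variant %||% "standard",
               reps = st$reps, seed = st$seed,
               families = st$families %||% family_names())
}

#' @rdname read_study_config
#' @export
write_study_config <- function(study, path) {
  stopifnot(inherits(study, "study_config"))
  yaml::write_yaml(list(
    study = list(mode = study$mode, bic_variant = study$bic_variant,
                 reps = study$reps, seed = study$seed,
                 families = study$families),
    scenarios = lapply(study$scenarios, scenario_to_list)), path,
    precision = 15)
  invisible(path)
}
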