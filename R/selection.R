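#' Select the preferred model for one replicate
#'
#' Chooses among the converged fits only: minimum AIC, minimum BIC, or
#' maximum log-likelihood.  Ties (probability zero with continuous data,
#' but tests need determinism) break first toward fewer parameters, then
#' toward canonical family order.
#'
#' @param fits List of `fit_result` objects for one replicate.
#' @param criterion `"aic"`, `"bic"` or `"loglik"`.
#' @param replicate Replicate id recorded in the output.
#' @return A one-row `data.frame` (`replicate`, `criterion`, `family`,
#'   `rmst`, `n_candidates`), or `NULL` if no fit converged (the replicate
#'   is excluded for this criterion).
#' @export
select_model <- function(fits, criterion = c("aic", "bic", "loglik"),
                         replicate = 1L) {
  criterion <- match.arg(criterion)
  conv <- Filter(function(x) isTRUE(x$converged), fits)
  if (length(conv) == 0) return(NULL)
  score <- vapply(conv, function(x)
    switch(criterion, aic = x$aic, bic = x$bic, loglik = -x$loglik),
    numeric(1))
  k <- vapply(conv, function(x) x$k, numeric(1))
  ord <- match(vapply(conv, function(x) x$family, character(1)), family_names())
  best <- order(score, k, ord)[1]
  chosen <- conv[[best]]
  data.frame(replicate = replicate, criterion = criterion,
             family = chosen$family, rmst = chosen$rmst_estimate,
             n_candidates = length(conv))
}

#' Selection frequencies per criterion
#'
#' @param records `data.frame` of selection records (rows from
#'   [select_model()], typically accumulated over replicates).
#' @return A `data.frame` (`criterion`, `family`, `n`, `share`); shares sum
#'   to 1 within each criterion over the included replicates.
#' @export
selection_frequencies <- function(records) {
  if (is.null(records) || nrow(records) == 0) stop("no selection records")
  out <- do.call(rbind, lapply(split(records, records$criterion), function(g) {
    tab <- table(factor(g$family, levels = family_names()))
    tab <- tab[tab > 0]
    data.frame(criterion = g$criterion[1], family = names(tab),
               n = as.integer(tab), share = as.numeric(tab) / nrow(g))
  }))
  rownames(out) <- NULL
  out
}

#' Agreement between two selection criteria
#'
#' Counts replicates on which two criteria chose the same family, and
#' evaluates the accuracy (share of RMST estimates within a tolerance band
#' of the truth) on that agreeing subset — answering whether agreement of
#' the criteria buys extra reliability.
#'
#' @param records Selection records covering both criteria.
#' @param true_rmst True RMST of the scenario (months).
#' @param criteria Length-2 character vector of criteria to compare.
#' @param band Half-width of the relative accuracy band (default 0.10).
#' @return List: `n_paired` (replicates with both criteria present),
#'   `n_agree`, `pct_agree`, `n_within_band` and `pct_within_band` on the
#'   agreeing subset.
#' @export
criteria_agreement <- function(records, true_rmst,
                               criteria = c("aic", "bic"), band = 0.10) {
  stopifnot(length(criteria) == 2)
  a <- records[records$criterion == criteria[1], ]
  b <- records[records$criterion == criteria[2], ]
  common <- intersect(a$replicate, b$replicate)
  a <- a[match(common, a$replicate), ]
  b <- b[match(common, b$replicate), ]
  agree <- a$family == b$family
  est <- a$rmst[agree]
  nw <- sum(abs(est - true_rmst) <= band * true_rmst)
  list(n_paired = length(common), n_agree = sum(agree),
       pct_agree = if (length(common)) 100 * mean(agree) else NA_real_,
       n_within_band = nw,
       pct_within_band = if (sum(agree)) 100 * nw / sum(agree) else NA_real_)
}
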