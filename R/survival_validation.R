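#' Score pN0 patients with the nodal staging score
#'
#' Attaches to every pN0 patient the probability that their negative
#' nodal staging is correct, given their T stage's fitted shapes and
#' adjusted LNM rate and their own examined-node count. Node-positive
#' patients are rejected: the score is defined only for pN0 diagnoses.
#'
#' @param cohort An `nss_cohort` containing pN0 patients only (subset
#'   upstream with `cohort[cohort$nodes_positive == 0, ]` keeps the
#'   class).
#' @param fits Named list of `nss_fit` per stage, as from
#'   [fit_cohort()].
#' @param rates Named list of `nss_adjusted_rate` per stage, as from
#'   [cohort_adjusted_rates()].
#' @return The input data.frame with an `nss` column appended.
#' @export
assign_nss <- function(cohort, fits, rates) {
  stopifnot(inherits(cohort, "nss_cohort"))
  if (any(cohort$nodes_positive >= 1L)) {
    stop("assign_nss is defined for pN0 patients only; remove pN+ rows")
  }
  need <- as.character(sort(unique(cohort$t_stage)))
  if (length(setdiff(need, names(fits))) ||
      length(setdiff(need, names(rates)))) {
    stop("fits/rates must cover every T stage present")
  }
  nss <- vapply(seq_len(nrow(cohort)), function(i) {
    t <- as.character(cohort$t_stage[i])
    nodal_staging_score(cohort$nodes_examined[i],
                        rates[[t]]$adjusted_rate,
                        fits[[t]]$alpha, fits[[t]]$beta)
  }, numeric(1))
  out <- cohort
  out$nss <- nss
  out
}

#' Quartile group assignment
#'
#' Splits scores into four groups at the sample quartiles. Values tied
#' with a quartile boundary go to the lower group (the score takes one
#' value per examined-node count within a stratum, so boundary ties are
#' common and the rule must be deterministic). With fewer than four
#' distinct values, fewer groups are formed with a warning.
#'
#' @param scores Numeric vector.
#' @return Integer vector of group labels starting at 1 (1 = lowest
#'   quartile).
#' @export
quartile_groups <- function(scores) {
  if (length(scores) == 0L) return(integer(0))
  qs <- unique(stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE))
  grp <- 1L + vapply(scores, function(s) sum(s > qs), 0L)
  if (length(unique(grp)) < 4L) {
    warning("fewer than 4 distinct quartile groups formed")
  }
  grp
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of disease-specific survival.
#'
#' @param times Non-negative survival times (months).
#' @param events Binary event indicators (1 = death from disease).
#' @param label Optional group label stored with the curve.
#' @return A list of class `nss_km`: `time` (ascending), `surv`
#'   (step-function values), `n_risk`, `label`.
#' @export
km_estimate <- function(times, events, label = NULL) {
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 label = label),
            class = "nss_km")
}

#' Log-rank comparison of survival across groups
#'
#' Observed-versus-expected chi-square test that the survival curves of
#' the groups coincide.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels (two or more distinct values).
#' @return A list with `statistic` (chi-square), `df`, `p_value`.
#' @export
log_rank <- function(times, events, groups) {
  stopifnot(length(times) == length(events), length(events) == length(groups))
  if (sum(events) == 0) stop("log-rank undefined: no events in any group")
  if (length(unique(groups)) < 2L) stop("need at least two groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ factor(groups))
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Survival at a fixed horizon from a KM curve
#'
#' @param km An `nss_km` curve.
#' @param t Horizon (same unit as the curve's times).
#' @return The step-function value at `t` (1 before the first event).
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "nss_km"))
  idx <- which(km$time <= t)
  if (length(idx) == 0L) return(1)
  km$surv[max(idx)]
}

#' End-to-end score-based survival validation
#'
#' The full verification loop on pN0 patients: score each patient,
#' group by pooled score quartiles (or within T stage), and compare the
#' groups' survival with Kaplan-Meier curves and a log-rank test. Under
#' the model, lower-scored pN0 patients harbour more undetected nodal
#' disease and should die sooner.
#'
#' @param cohort An `nss_cohort` (pN+ rows are dropped internally).
#' @param fits,rates Per-stage fits and adjusted rates.
#' @param within_stage If `TRUE`, quartiles are computed within each T
#'   stage instead of pooled (default pooled).
#' @return A list with `scored` (pN0 rows + `nss` + `quartile`), `km`
#'   (list of `nss_km` per quartile), and `logrank`.
#' @export
validate_survival <- function(cohort, fits, rates, within_stage = FALSE) {
  pn0 <- cohort[cohort$nodes_positive == 0L, , drop = FALSE]
  class(pn0) <- c("nss_cohort", "data.frame")
  scored <- assign_nss(pn0, fits, rates)
  if (within_stage) {
    scored$quartile <- NA_integer_
    for (t in unique(scored$t_stage)) {
      idx <- scored$t_stage == t
      scored$quartile[idx] <- quartile_groups(scored$nss[idx])
    }
  } else {
    scored$quartile <- quartile_groups(scored$nss)
  }
  km <- lapply(sort(unique(scored$quartile)), function(q) {
    rows <- scored[scored$quartile == q, ]
    km_estimate(rows$survival_months, rows$event, label = paste0("Q", q))
  })
  lr <- log_rank(scored$survival_months, scored$event, scored$quartile)
  list(scored = scored, km = km, logrank = lr)
}
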