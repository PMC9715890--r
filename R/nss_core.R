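#' Probability that a node-positive patient shows no positive node
#'
#' The false-negative probability for a patient with latent nodal
#' metastasis in whom `e` examined nodes were all negative:
#' `Be(alpha, beta + e) / Be(alpha, beta)`, i.e. the beta-binomial mass
#' at zero. Equals 1 at `e = 0` (no information) and decreases strictly
#' towards 0 as more nodes are examined.
#'
#' @param e Integer vector of examined-node counts, `e >= 0`.
#' @param alpha,beta Positive shapes from the stratum fit.
#' @return Probability vector, same length as `e`.
#' @export
prob_false_negative <- function(e, alpha, beta) {
  if (any(e < 0)) stop("e must be non-negative")
  if (alpha <= 0 || beta <= 0) stop("shape parameters must be positive")
  exp(lbeta(alpha, beta + e) - lbeta(alpha, beta))
}

#' Estimated number of false-negative pN0 patients at one node count
#'
#' Scales the observed node-positive count at examined-node count `e` by
#' the false-negative odds, capped at the number of pN0 patients
#' actually observed there (the estimate cannot exceed the patients
#' available to reclassify): `min(p_fn * tp / (1 - p_fn), n)`. At
#' `p_fn = 1` the cap's limit `n` is returned.
#'
#' @param p_fn False-negative probability at this `e`.
#' @param tp Observed node-positive patients at this `e` (including
#'   those with every node positive).
#' @param n Observed node-negative (pN0) patients at this `e`.
#' @return Non-negative real, at most `n`. Vectorised over its
#'   arguments.
#' @export
estimate_false_negatives <- function(p_fn, tp, n) {
  k <- max(length(p_fn), length(tp), length(n))
  p_fn <- rep_len(p_fn, k); tp <- rep_len(tp, k); n <- rep_len(n, k)
  if (any(p_fn < 0 | p_fn > 1)) stop("p_fn must lie in [0, 1]")
  if (any(tp < 0) || any(n < 0)) stop("counts must be non-negative")
  est <- ifelse(p_fn >= 1, n, p_fn * tp / (1 - p_fn))
  pmin(est, n)
}

#' LNM rate adjusted for estimated false-negative pN0 patients
#'
#' Reclassifies the estimated false negatives as node positive:
#' `adjusted = (sum FN + sum TP) / (sum N + sum TP)` where the sums run
#' over observed examined-node counts, `N` is the pN0 tally and the
#' denominator uses the identity `sum FN + sum TN = sum N`. The raw rate
#' `sum TP / (sum N + sum TP)` is returned alongside; the adjustment can
#' only increase the rate.
#'
#' @param fn_by_e,tp_by_e,n_by_e Numeric vectors over the same ascending
#'   `e` grid: estimated false negatives, node-positive tallies, pN0
#'   tallies.
#' @param t_stage Optional stage label.
#' @return A list of class `nss_adjusted_rate` with `t_stage`,
#'   `raw_rate`, `adjusted_rate`, `increase`.
#' @export
adjusted_rate <- function(fn_by_e, tp_by_e, n_by_e, t_stage = NA_integer_) {
  stopifnot(length(fn_by_e) == length(tp_by_e),
            length(tp_by_e) == length(n_by_e))
  if (any(fn_by_e > n_by_e + 1e-9)) stop("fn exceeds pN0 count at some e")
  total <- sum(n_by_e) + sum(tp_by_e)
  if (total == 0) stop("LNM rate undefined: empty stratum")
  raw <- sum(tp_by_e) / total
  adj <- (sum(fn_by_e) + sum(tp_by_e)) / total
  structure(list(t_stage = t_stage, raw_rate = raw, adjusted_rate = adj,
                 increase = adj - raw),
            class = "nss_adjusted_rate")
}

#' Nodal staging score
#'
#' Posterior probability that a patient staged pN0 after `e` examined
#' nodes is truly node negative, given the stratum's (adjusted) LNM
#' prevalence `rate`:
#' `(1 - rate) / ((1 - rate) + rate * P(FN | e))`.
#' Starts at `1 - rate` when `e = 0` (the prior) and increases towards 1
#' as examined nodes accumulate and a missed metastasis becomes
#' implausible.
#'
#' @param e Integer vector of examined-node counts, `e >= 0`.
#' @param rate LNM prevalence in `(0, 1)` (the adjusted rate of the
#'   stratum).
#' @param alpha,beta Positive shapes from the stratum fit.
#' @return Probability vector.
#' @export
nodal_staging_score <- function(e, rate, alpha, beta) {
  if (rate <= 0 || rate >= 1) stop("rate must lie strictly in (0, 1)")
  p_fn <- prob_false_negative(e, alpha, beta)
  (1 - rate) / ((1 - rate) + rate * p_fn)
}

#' Minimum lymphadenectomy extent reaching a target score
#'
#' Smallest number of examined nodes `e` whose nodal staging score
#' exceeds `threshold` (strict inequality by default, i.e. "score above
#' 90%"). Returns 0 with a warning when the prior `1 - rate` already
#' exceeds the threshold, and `NA` (with the score reached at `e_max`
#' attached as attribute `nss_at_e_max`) when no `e <= e_max` attains
#' it.
#'
#' @inheritParams nodal_staging_score
#' @param threshold Target score in `(0, 1)`, default 0.90.
#' @param e_max Search limit, default 200.
#' @param strict Use `>` (default) or `>=` for the comparison.
#' @return Integer count of examined nodes, or `NA_integer_` when not
#'   attainable within `e_max`.
#' @export
adequate_lne <- function(rate, alpha, beta, threshold = 0.90, e_max = 200,
                         strict = TRUE) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  # 1e-9 guard so scores that equal the threshold in exact arithmetic
  # (e.g. the uniform-shape closed form at a rational boundary) are not
  # re-classified by floating-point noise
  cmp <- if (strict) {
    function(x, y) x > y + 1e-9
  } else {
    function(x, y) x >= y - 1e-9
  }
  if (cmp(1 - rate, threshold)) {
    warning("prior probability 1 - rate already exceeds the threshold")
    return(0L)
  }
  e_grid <- 0:e_max
  nss <- nodal_staging_score(e_grid, rate, alpha, beta)
  hit <- which(cmp(nss, threshold))
  if (length(hit) == 0L) {
    out <- NA_integer_
    attr(out, "nss_at_e_max") <- nss[length(nss)]
    return(out)
  }
  e_grid[hit[1]]
}

#' Full per-stage score table
#'
#' For every T stage present in the cohort, tabulates over examined-node
#' counts `e = 1..e_max`: the false-negative probability, the observed
#' node-positive and pN0 tallies, the capped false-negative estimate,
#' and the nodal staging score computed with the stratum's adjusted
#' rate. Tallies are zero at unobserved `e`; probabilities and scores
#' are defined on the whole grid.
#'
#' @param cohort An `nss_cohort`.
#' @param fits Named list of `nss_fit` objects as from [fit_cohort()],
#'   covering every stage present.
#' @param e_max Upper end of the `e` grid; default the largest observed
#'   examined-node count per stratum.
#' @return A data.frame of class `nss_table` with columns `t_stage`,
#'   `e`, `p_fn`, `fn_est`, `tp`, `n`, `nss`, plus the per-stage
#'   adjusted rates as attribute `rates` (named list of
#'   `nss_adjusted_rate`).
#' @export
build_nss_table <- function(cohort, fits, e_max = NULL) {
  stopifnot(inherits(cohort, "nss_cohort"))
  stages <- sort(unique(cohort$t_stage))
  missing_fit <- setdiff(as.character(stages), names(fits))
  if (length(missing_fit)) {
    stop("no fit provided for T stage(s): ",
         paste(missing_fit, collapse = ", "))
  }
  rates <- list()
  rows <- lapply(stages, function(t) {
    fit <- fits[[as.character(t)]]
    tal <- stratum_tallies(cohort, t)
    top <- if (is.null(e_max)) max(tal$e) else e_max
    e_grid <- seq_len(top)
    tp <- n <- integer(top)
    tp[tal$e[tal$e <= top]] <- tal$tp[tal$e <= top]
    n[tal$e[tal$e <= top]] <- tal$n[tal$e <= top]
    p_fn <- prob_false_negative(e_grid, fit$alpha, fit$beta)
    fn <- estimate_false_negatives(p_fn, tp, n)
    # adjusted rate uses the observed-e tallies only
    p_obs <- prob_false_negative(tal$e, fit$alpha, fit$beta)
    fn_obs <- estimate_false_negatives(p_obs, tal$tp, tal$n)
    ar <- adjusted_rate(fn_obs, tal$tp, tal$n, t_stage = t)
    rates[[as.character(t)]] <<- ar
    data.frame(t_stage = t, e = e_grid, p_fn = p_fn, fn_est = fn,
               tp = tp, n = n,
               nss = nodal_staging_score(e_grid, ar$adjusted_rate,
                                         fit$alpha, fit$beta))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rates") <- rates
  class(out) <- c("nss_table", "data.frame")
  out
}

#' Adjusted rates for every stratum of a cohort
#'
#' Convenience wrapper: tallies, false-negative estimates and
#' [adjusted_rate()] per T stage.
#'
#' @inheritParams build_nss_table
#' @return Named list of `nss_adjusted_rate`, one per stage present.
#' @export
cohort_adjusted_rates <- function(cohort, fits) {
  tab <- build_nss_table(cohort, fits)
  attr(tab, "rates")
}

#' @export
print.nss_adjusted_rate <- function(x, ...) {
  cat(sprintf("T%s LNM rate: raw %.3f -> adjusted %.3f (+%.3f)\n",
              x$t_stage, x$raw_rate, x$adjusted_rate, x$increase))
  invisible(x)
}
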