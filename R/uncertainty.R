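#' Stratified bootstrap confidence intervals
#'
#' Resamples patients with replacement within each T stratum (pN0 and
#' pN+ patients jointly, preserving stratum size), refits the
#' beta-binomial shapes and recomputes the raw rate, the false-negative
#' correction and the adjusted rate on every replicate, and returns
#' percentile intervals for alpha, beta, raw rate, adjusted rate, and
#' the rate increase per stratum. Joint resampling propagates the
#' uncertainty in rates and shapes coherently; the increase interval is
#' formed from the per-replicate differences, not by interval
#' arithmetic.
#'
#' Replicates whose fit fails (e.g. a resample with fewer than two
#' usable pN+ pairs) are dropped and counted; more than 10% failures is
#' an error. Results are deterministic given `seed`: the master seed
#' spawns one sub-seed per replicate, so the replicate stream does not
#' depend on evaluation order.
#'
#' @param cohort An `nss_cohort` with at least one pN+ patient per
#'   stratum.
#' @param n_boot Number of bootstrap replicates (>= 2); 1000 mirrors the
#'   precision analysis the score was published with.
#' @param seed Integer master seed.
#' @param level Confidence level, default 0.95 (percentile 2.5/97.5).
#' @return A data.frame of class `nss_bootstrap`: one row per
#'   (stratum, statistic) with `t_stage`, `statistic`, `point` (the
#'   full-cohort estimate), `ci_low`, `ci_high`, `n_boot`, `n_failed`,
#'   `seed`. A warning (never an error) is raised if a percentile
#'   interval excludes its point estimate, which can happen on skewed
#'   statistics.
#' @export
bootstrap_statistics <- function(cohort, n_boot = 1000, seed = 1L,
                                 level = 0.95) {
  stopifnot(inherits(cohort, "nss_cohort"), n_boot >= 2)
  stages <- sort(unique(cohort$t_stage))
  strata <- lapply(stages, function(t) cohort[cohort$t_stage == t, ])
  names(strata) <- as.character(stages)

  stat_one <- function(rows) {
    pos <- rows[rows$nodes_positive >= 1L, ]
    fit <- fit_betabinom(pos$nodes_positive, pos$nodes_examined)
    tal <- stratum_tallies_df(rows)
    p_fn <- prob_false_negative(tal$e, fit$alpha, fit$beta)
    fn <- estimate_false_negatives(p_fn, tal$tp, tal$n)
    ar <- adjusted_rate(fn, tal$tp, tal$n)
    c(alpha = fit$alpha, beta = fit$beta, raw_rate = ar$raw_rate,
      adjusted_rate = ar$adjusted_rate, increase = ar$increase)
  }

  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, n_boot)

  out <- lapply(stages, function(t) {
    rows <- strata[[as.character(t)]]
    point <- stat_one(rows)
    reps <- matrix(NA_real_, n_boot, length(point),
                   dimnames = list(NULL, names(point)))
    n_failed <- 0L
    for (b in seq_len(n_boot)) {
      set.seed(sub_seeds[b])
      idx <- sample.int(nrow(rows), nrow(rows), replace = TRUE)
      val <- tryCatch(stat_one(rows[idx, , drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(val)) n_failed <- n_failed + 1L else reps[b, ] <- val
    }
    if (n_failed > 0.10 * n_boot) {
      stop("bootstrap unstable in T stage ", t, ": ", n_failed, "/",
           n_boot, " replicate fits failed")
    }
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    qs <- apply(reps, 2, stats::quantile, probs = probs, na.rm = TRUE)
    res <- data.frame(
      t_stage = t,
      statistic = names(point),
      point = unname(point),
      ci_low = unname(qs[1, ]),
      ci_high = unname(qs[2, ]),
      n_boot = n_boot,
      n_failed = n_failed,
      seed = as.integer(seed),
      stringsAsFactors = FALSE
    )
    outside <- res$point < res$ci_low | res$point > res$ci_high
    if (any(outside)) {
      warning("percentile interval excludes the point estimate for ",
              paste(res$statistic[outside], collapse = ", "),
              " in T stage ", t)
    }
    res
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("nss_bootstrap", "data.frame")
  res
}

# tallies from a plain stratum data.frame (no cohort class requirement,
# used on bootstrap resamples)
stratum_tallies_df <- function(rows) {
  e_vals <- sort(unique(rows$nodes_examined))
  pos <- rows$nodes_positive >= 1L
  data.frame(
    e  = e_vals,
    tp = vapply(e_vals, function(e) sum(rows$nodes_examined == e & pos), 0L),
    n  = vapply(e_vals, function(e) sum(rows$nodes_examined == e & !pos), 0L)
  )
}
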